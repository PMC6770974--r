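#' @import methods
#' @importFrom Biostrings AAStringSet DNAStringSet width
NULL

#' Gene catalog: transcripts, coordinates and sequences of an annotated genome
#'
#' Container for the parsed annotation of one genome: one row per transcript
#' (with a parent-locus link), per-transcript exon intervals, and the peptide
#' and CDS sequences that could be resolved from the supplied FASTA files.
#' Coordinates are stored 1-based inclusive, as in GFF3; internal window
#' arithmetic elsewhere in the package is 0-based half-open and converts at
#' the boundary.
#'
#' @slot transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{chromosome}, \code{start}, \code{end},
#'   \code{strand}, \code{n_exons}, \code{cds_ok}.
#' @slot exons named list (by transcript id) of two-column integer matrices
#'   \code{start}, \code{end}; rows sorted and non-overlapping.
#' @slot peptide \code{AAStringSet} named by transcript id.
#' @slot cds \code{DNAStringSet} named by transcript id; only in-frame
#'   (length divisible by three) sequences are retained here.
#'
#' @seealso [loadAnnotation()], [selectFamily()]
#' @exportClass GeneCatalog
setClass("GeneCatalog",
  representation(
    transcripts = "data.frame",
    exons       = "list",
    peptide     = "AAStringSet",
    cds         = "DNAStringSet"
  )
)

setValidity("GeneCatalog", function(object) {
  tx <- object@transcripts
  need <- c("transcript_id", "gene_id", "chromosome", "start", "end",
            "strand", "n_exons", "cds_ok")
  if (!all(need %in% names(tx)))
    return(paste("transcripts must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tx$transcript_id))
    return("duplicated transcript ids")
  if (any(tx$start > tx$end))
    return("transcript with start > end")
  if (!all(tx$strand %in% c("+", "-")))
    return("strand must be '+' or '-'")
  for (id in names(object@exons)) {
    ex <- object@exons[[id]]
    if (nrow(ex) > 1) {
      if (is.unsorted(ex[, 1L]))
        return(sprintf("exons of %s not sorted", id))
      if (any(ex[-1L, 1L] <= ex[-nrow(ex), 2L]))
        return(sprintf("overlapping exons in %s", id))
    }
    if (any(ex[, 1L] > ex[, 2L]))
      return(sprintf("exon with start > end in %s", id))
  }
  if (length(object@cds) && any(Biostrings::width(object@cds) %% 3L != 0L))
    return("CDS length not divisible by 3")
  TRUE
})

#' Family catalog: loci passing the three-domain membership rule
#'
#' One representative transcript per member locus, with the basic protein and
#' gene-structure properties reported for gene-family surveys: peptide length
#' (aa), molecular weight (Da), isoelectric point, exon count.
#'
#' @slot members data.frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{chromosome}, \code{start}, \code{end}, \code{strand},
#'   \code{length_aa}, \code{mw_da}, \code{pi}, \code{exons}.
#' @slot evalueMax numeric(1), the domain-hit E-value cutoff applied.
#'
#' @seealso [selectFamily()], [chromosomeDistribution()]
#' @exportClass FamilyCatalog
setClass("FamilyCatalog",
  representation(members = "data.frame", evalueMax = "numeric")
)

setValidity("FamilyCatalog", function(object) {
  m <- object@members
  need <- c("gene_id", "transcript_id", "chromosome", "start", "end",
            "strand", "length_aa", "mw_da", "pi", "exons")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$gene_id))
    return("one member per locus: duplicated gene_id")
  if (length(object@evalueMax) != 1L || object@evalueMax < 0)
    return("evalueMax must be a single nonnegative number")
  TRUE
})

#' Variant panel: biallelic SNP genotypes for a two-population accession set
#'
#' Sites-by-accessions genotype store used by the diversity scan. For each
#' site and accession the number of called alleles (\code{an}, 0/1/2; 1 means
#' a half-missing diploid call) and the alt-allele count among those called
#' (\code{ac}) are kept, so missing and half-missing data are handled
#' explicitly.
#'
#' @slot chrom character, per-site chromosome.
#' @slot pos integer, per-site 1-based position; strictly increasing within a
#'   chromosome.
#' @slot ref,alt character, per-site alleles (biallelic after normalization).
#' @slot ac,an integer matrices, sites x accessions.
#' @slot populations factor named by accession, levels typically
#'   \code{wild}/\code{cultivated}.
#'
#' @seealso [readVcfPanel()], [filterVariants()], [windowPi()]
#' @exportClass VariantPanel
setClass("VariantPanel",
  representation(
    chrom = "character", pos = "integer",
    ref = "character", alt = "character",
    ac = "matrix", an = "matrix",
    populations = "factor"
  )
)

setValidity("VariantPanel", function(object) {
  ns <- length(object@pos)
  if (length(object@chrom) != ns || length(object@ref) != ns ||
      length(object@alt) != ns)
    return("per-site slots must have equal length")
  if (nrow(object@ac) != ns || nrow(object@an) != ns)
    return("genotype matrices must have one row per site")
  if (!identical(dim(object@ac), dim(object@an)))
    return("ac and an must have identical dimensions")
  if (ncol(object@an) != length(object@populations))
    return("one population label per accession")
  if (is.null(colnames(object@an)) ||
      !identical(colnames(object@an), names(object@populations)))
    return("accession names of genotype matrices and populations must match")
  if (any(object@an < 0L | object@an > 2L))
    return("an must be in 0..2")
  if (any(object@ac < 0L | object@ac > object@an))
    return("ac must satisfy 0 <= ac <= an")
  for (ch in unique(object@chrom)) {
    p <- object@pos[object@chrom == ch]
    if (any(diff(p) <= 0L))
      return(sprintf("positions not strictly increasing on %s", ch))
  }
  TRUE
})

#' @describeIn GeneCatalog-class compact display
#' @param object a \code{GeneCatalog}
#' @export
setMethod("show", "GeneCatalog", function(object) {
  tx <- object@transcripts
  cat(sprintf("GeneCatalog: %d loci, %d transcripts on %d sequences\n",
              length(unique(tx$gene_id)), nrow(tx),
              length(unique(tx$chromosome))))
  cat(sprintf("  peptides: %d, in-frame CDS: %d\n",
              length(object@peptide), length(object@cds)))
})

#' @describeIn FamilyCatalog-class compact display
#' @param object a \code{FamilyCatalog}
#' @export
setMethod("show", "FamilyCatalog", function(object) {
  m <- object@members
  cat(sprintf("FamilyCatalog: %d members (E-value <= %g)\n",
              nrow(m), object@evalueMax))
  if (nrow(m))
    cat(sprintf("  peptide length %d-%d aa on %d sequences\n",
                min(m$length_aa), max(m$length_aa),
                length(unique(m$chromosome))))
})

#' @describeIn VariantPanel-class compact display
#' @param object a \code{VariantPanel}
#' @export
setMethod("show", "VariantPanel", function(object) {
  cat(sprintf("VariantPanel: %d sites, %d accessions (%s)\n",
              length(object@pos), ncol(object@an),
              paste(sprintf("%s: %d", levels(object@populations),
                            tabulate(object@populations)), collapse = ", ")))
})

#' Accessors for package classes
#'
#' \code{transcriptTable} returns the transcript-level table of a
#' \code{GeneCatalog}; \code{exonsOf} the exon matrix of one transcript;
#' \code{peptides}/\code{cdsSeqs} the sequence sets. \code{familyMembers}
#' returns the per-member property table of a \code{FamilyCatalog}.
#' \code{accessions}/\code{populationsOf}/\code{positionsOf} expose the
#' sample and site annotation of a \code{VariantPanel}.
#'
#' @param x a package object
#' @param transcript transcript id
#' @return the underlying table, matrix or vector (copies; slots are not
#'   meant to be touched directly)
#' @name accessors
NULL

#' @rdname accessors
#' @export
transcriptTable <- function(x) {
  stopifnot(is(x, "GeneCatalog"))
  x@transcripts
}

#' @rdname accessors
#' @export
exonsOf <- function(x, transcript) {
  stopifnot(is(x, "GeneCatalog"))
  ex <- x@exons[[transcript]]
  if (is.null(ex)) stop("unknown transcript: ", transcript)
  ex
}

#' @rdname accessors
#' @export
peptides <- function(x) {
  stopifnot(is(x, "GeneCatalog"))
  x@peptide
}

#' @rdname accessors
#' @export
cdsSeqs <- function(x) {
  stopifnot(is(x, "GeneCatalog"))
  x@cds
}

#' @rdname accessors
#' @export
familyMembers <- function(x) {
  stopifnot(is(x, "FamilyCatalog"))
  x@members
}

#' @rdname accessors
#' @export
accessions <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  colnames(x@an)
}

#' @rdname accessors
#' @export
populationsOf <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  x@populations
}

#' @rdname accessors
#' @export
positionsOf <- function(x) {
  stopifnot(is(x, "VariantPanel"))
  data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref, alt = x@alt,
             stringsAsFactors = FALSE)
}
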