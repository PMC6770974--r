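#' Load a gene catalog from GFF3 annotation plus peptide/CDS FASTA
#'
#' Parses gene/mRNA/exon records from a GFF3 file and attaches peptide and
#' CDS sequences by transcript id. All transcripts of a locus are retained at
#' this stage with a parent-locus link; representative-transcript selection
#' happens later in [selectFamily()]. A CDS whose length is not divisible by
#' three is flagged (\code{cds_ok = FALSE}), its sequence left unset, and the
#' gene retained.
#'
#' @param gff3_path path to a GFF3 file (gene/mRNA/exon records; mRNA
#'   \code{Parent} links to the gene)
#' @param pep_path,cds_path FASTA files whose sequence names resolve to mRNA
#'   ids (anything after the first whitespace in a FASTA header is ignored)
#' @return a [GeneCatalog-class]
#' @export
loadAnnotation <- function(gff3_path, pep_path = NULL, cds_path = NULL) {
  .checkGff3(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  type <- as.character(gr$type)
  is_mrna <- type %in% c("mRNA", "transcript")
  is_gene <- type == "gene"
  is_exon <- type == "exon"
  if (!any(is_mrna)) stop("no mRNA/transcript records in ", gff3_path)

  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1))

  mr <- gr[is_mrna]
  tx <- data.frame(
    transcript_id = as.character(mr$ID),
    gene_id = first_parent(mr$Parent),
    chromosome = as.character(GenomicRanges::seqnames(mr)),
    start = GenomicRanges::start(mr),
    end = GenomicRanges::end(mr),
    strand = as.character(GenomicRanges::strand(mr)),
    stringsAsFactors = FALSE
  )
  if (anyNA(tx$gene_id)) {
    # orphan transcripts become their own locus
    orphan <- is.na(tx$gene_id)
    tx$gene_id[orphan] <- tx$transcript_id[orphan]
  }
  # exons grouped by parent transcript, reported in genomic order
  ex <- gr[is_exon]
  ex_parent <- first_parent(ex$Parent)
  exons <- lapply(split(seq_along(ex), ex_parent), function(i) {
    m <- cbind(start = GenomicRanges::start(ex)[i],
               end = GenomicRanges::end(ex)[i])
    m[order(m[, 1L]), , drop = FALSE]
  })
  missing_ex <- setdiff(tx$transcript_id, names(exons))
  if (length(missing_ex)) {
    # single-exon transcripts annotated without explicit exon rows
    one <- lapply(missing_ex, function(id) {
      r <- tx[tx$transcript_id == id, ]
      cbind(start = r$start, end = r$end)
    })
    names(one) <- missing_ex
    exons <- c(exons, one)
  }
  tx$n_exons <- vapply(tx$transcript_id,
                       function(id) nrow(exons[[id]]), integer(1))

  pep <- Biostrings::AAStringSet()
  if (!is.null(pep_path)) {
    pep <- Biostrings::readAAStringSet(pep_path)
    names(pep) <- sub("\\s.*$", "", names(pep))
    pep <- pep[names(pep) %in% tx$transcript_id]
  }
  cds <- Biostrings::DNAStringSet()
  tx$cds_ok <- FALSE
  if (!is.null(cds_path)) {
    cds <- Biostrings::readDNAStringSet(cds_path)
    names(cds) <- sub("\\s.*$", "", names(cds))
    cds <- cds[names(cds) %in% tx$transcript_id]
    inframe <- Biostrings::width(cds) %% 3L == 0L
    if (any(!inframe))
      warning("CDS length not divisible by 3, sequence unset for: ",
              paste(names(cds)[!inframe], collapse = ", "))
    cds <- cds[inframe]
    tx$cds_ok <- tx$transcript_id %in% names(cds)
  }
  rownames(tx) <- NULL
  new("GeneCatalog", transcripts = tx, exons = exons[tx$transcript_id],
      peptide = pep, cds = cds)
}

# cheap structural pre-scan so malformed lines are reported by number
.checkGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    stop(sprintf("GFF3 parse error at line %d of %s: expected 9 tab-separated fields, found %d",
                 bad, path, nf[nf != 9L][1L]))
  }
  invisible(TRUE)
}

#' Read a tabular domain-hit file
#'
#' One hit per row with header
#' \code{gene_id  domain  e_value  qstart  qend}; \code{gene_id} holds the
#' transcript (peptide) id the domain was found on.
#'
#' @param path TSV path
#' @return data.frame of hits
#' @export
readDomainHits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "domain", "e_value", "qstart", "qend")
  if (!all(need %in% names(h)))
    stop("domain-hit table must have columns: ", paste(need, collapse = ", "))
  if (any(h$e_value < 0)) stop("negative E-value in domain-hit table")
  if (any(h$qstart > h$qend)) stop("domain hit with qstart > qend")
  h
}

# the three-domain architecture that defines a canonical laccase-type
# multicopper oxidase
.FAMILY_DOMAINS <- c("CuOx", "CuOx2", "CuOx3")

.hasCompleteOrf <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L || n < 6L) return(FALSE)
  codons <- substring(cds, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  stops <- c("TAA", "TAG", "TGA")
  codons[1L] == "ATG" &&
    codons[length(codons)] %in% stops &&
    !any(codons[-length(codons)] %in% stops)
}

#' Apply the three-domain family-membership rule
#'
#' A locus is a family member iff at least one of its transcripts carries all
#' three Cu-oxidase domains (each hit at E-value below the cutoff) and has a
#' complete coding sequence (starts with ATG, ends with a stop, no internal
#' stop, length divisible by three). Among several qualifying transcripts of
#' one locus exactly one is kept: the longest peptide, ties broken by the
#' lexicographically smallest transcript id. Loci with only one or two of the
#' typical domains are excluded.
#'
#' @param catalog a [GeneCatalog-class]
#' @param hits domain-hit data.frame as from [readDomainHits()]; hits are
#'   keyed by transcript id
#' @param evalue_max E-value cutoff, default \code{1e-5}
#' @return a [FamilyCatalog-class] with per-member properties
#' @export
selectFamily <- function(catalog, hits, evalue_max = 1e-5) {
  stopifnot(is(catalog, "GeneCatalog"))
  tx <- catalog@transcripts
  unknown <- setdiff(unique(hits$gene_id), tx$transcript_id)
  if (length(unknown))
    stop("domain hits reference unknown ids: ", paste(unknown, collapse = ", "))
  ok_hits <- hits[hits$e_value <= evalue_max &
                  hits$domain %in% .FAMILY_DOMAINS, , drop = FALSE]
  dom_by_tx <- lapply(split(ok_hits$domain, ok_hits$gene_id), unique)
  three <- names(dom_by_tx)[vapply(dom_by_tx, function(d)
    all(.FAMILY_DOMAINS %in% d), logical(1))]

  cds <- catalog@cds
  complete <- names(cds)[vapply(as.character(cds), .hasCompleteOrf, logical(1))]
  qual <- intersect(three, complete)
  qual <- qual[qual %in% names(catalog@peptide)]
  if (!length(qual))
    return(new("FamilyCatalog", members = .emptyMembers(),
               evalueMax = evalue_max))

  qt <- tx[tx$transcript_id %in% qual, , drop = FALSE]
  qt$pep_len <- Biostrings::width(catalog@peptide[qt$transcript_id])
  # representative per locus: longest peptide, then lexicographic id
  qt <- qt[order(qt$gene_id, -qt$pep_len, qt$transcript_id), , drop = FALSE]
  rep <- qt[!duplicated(qt$gene_id), , drop = FALSE]

  props <- lapply(as.character(catalog@peptide[rep$transcript_id]),
                  proteinProperties)
  members <- data.frame(
    gene_id = rep$gene_id,
    transcript_id = rep$transcript_id,
    chromosome = rep$chromosome,
    start = rep$start, end = rep$end, strand = rep$strand,
    length_aa = vapply(props, `[[`, integer(1), "length_aa"),
    mw_da = vapply(props, `[[`, numeric(1), "mw_da"),
    pi = vapply(props, `[[`, numeric(1), "pi"),
    exons = rep$n_exons,
    stringsAsFactors = FALSE
  )
  members <- members[order(members$gene_id), , drop = FALSE]
  rownames(members) <- NULL
  new("FamilyCatalog", members = members, evalueMax = evalue_max)
}

.emptyMembers <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chromosome = character(), start = integer(), end = integer(),
             strand = character(), length_aa = integer(), mw_da = numeric(),
             pi = numeric(), exons = integer(), stringsAsFactors = FALSE)
}

#' Per-chromosome member counts
#'
#' Counts family members per chromosome; members placed on unanchored
#' scaffolds (sequence name containing \code{scaffold}, case-insensitive) are
#' reported separately.
#'
#' @param x a [FamilyCatalog-class] or a data.frame with columns
#'   \code{gene_id} and \code{chromosome}
#' @return list with \code{chromosomes} (named integer vector),
#'   \code{scaffolds} (named integer vector) and \code{max_count}, the
#'   largest chromosome-placed count (0 for an empty catalog)
#' @export
chromosomeDistribution <- function(x) {
  m <- if (is(x, "FamilyCatalog")) familyMembers(x) else x
  stopifnot(is.data.frame(m), "chromosome" %in% names(m))
  if (!nrow(m))
    return(list(chromosomes = integer(0), scaffolds = integer(0),
                max_count = 0L))
  sca <- grepl("scaffold", m$chromosome, ignore.case = TRUE)
  tab <- function(v) { t <- table(v); stats::setNames(as.integer(t), names(t)) }
  chromosomes <- tab(m$chromosome[!sca])
  scaffolds <- tab(m$chromosome[sca])
  list(chromosomes = chromosomes, scaffolds = scaffolds,
       max_count = if (length(chromosomes)) max(chromosomes) else 0L)
}

#' Exon/intron organization of a transcript
#'
#' @param catalog a [GeneCatalog-class]
#' @param transcript transcript id
#' @return list with \code{exon_count}, \code{intron_count}
#'   (\code{exon_count - 1}) and \code{has_utr} (exon span extends beyond the
#'   CDS span; \code{NA} when no in-frame CDS is attached)
#' @export
exonProfile <- function(catalog, transcript) {
  ex <- exonsOf(catalog, transcript)
  n <- nrow(ex)
  has_utr <- NA
  if (transcript %in% names(catalog@cds)) {
    exon_len <- sum(ex[, 2L] - ex[, 1L] + 1L)
    has_utr <- exon_len > Biostrings::width(catalog@cds[transcript])
  }
  list(exon_count = n, intron_count = n - 1L, has_utr = has_utr)
}

#' Write a family catalog to TSV
#'
#' Columns: \code{gene_id chromosome start end strand length_aa mw_da pi
#' exons}.
#'
#' @param fc a [FamilyCatalog-class]
#' @param path output path
#' @export
writeCatalog <- function(fc, path) {
  m <- familyMembers(fc)
  out <- m[, c("gene_id", "chromosome", "start", "end", "strand",
               "length_aa", "mw_da", "pi", "exons")]
  out$mw_da <- round(out$mw_da, 2)
  out$pi <- round(out$pi, 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
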