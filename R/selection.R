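# Two-population nucleotide-diversity scan: SNP filtering, sliding-window
# pi, pi-ratio with chromosome baselines, top-5% sweep calling, and an
# identity-by-state accession tree. Window coordinates are 0-based half-open
# internally; the VCF and BED boundaries convert on entry.

#' Build a variant panel from genotype components
#'
#' Low-level constructor used by the readers and the synthetic generator.
#'
#' @param chrom,pos,ref,alt per-site vectors (positions 1-based, strictly
#'   increasing within a chromosome)
#' @param ac,an integer matrices sites x accessions: alt-allele count among
#'   called alleles, and number of called alleles (0, 1 or 2)
#' @param populations factor (or character) named by accession
#' @return a [VariantPanel-class]
#' @export
makeVariantPanel <- function(chrom, pos, ref, alt, ac, an, populations) {
  if (is.character(populations))
    populations <- factor(populations)
  new("VariantPanel", chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      ac = ac, an = an, populations = populations)
}

#' Read a VCF plus a population-assignment table into a variant panel
#'
#' Biallelic SNP sites only: sites with more than one ALT allele are dropped
#' with a warning. Diploid GT fields are parsed allele-wise, so half-missing
#' calls (e.g. \code{0/.}) contribute their called allele.
#'
#' @param vcf_path VCF file (plain text or gzipped)
#' @param pop_path TSV with header \code{accession population}
#' @return a [VariantPanel-class] restricted to accessions present in the
#'   population table
#' @export
readVcfPanel <- function(vcf_path, pop_path) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  pops <- utils::read.delim(pop_path, stringsAsFactors = FALSE)
  if (!all(c("accession", "population") %in% names(pops)))
    stop("population table must have columns: accession, population")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- intersect(colnames(gt), pops$accession)
  if (!length(keep)) stop("no VCF sample matches the population table")
  gt <- gt[, keep, drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  called1 <- a1 %in% c("0", "1")
  called2 <- a2 %in% c("0", "1")
  an <- matrix(as.integer(called1) + as.integer(called2), nrow = nrow(gt))
  ac <- matrix(as.integer(called1 & a1 == "1") +
               as.integer(called2 & a2 == "1"), nrow = nrow(gt))
  dimnames(ac) <- dimnames(an) <- list(NULL, colnames(gt))
  popf <- factor(stats::setNames(pops$population, pops$accession)[keep])
  names(popf) <- keep
  makeVariantPanel(fix[, "CHROM"], as.integer(fix[, "POS"]),
                   fix[, "REF"], fix[, "ALT"], ac, an, popf)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' Both statistics are computed over the combined panel (all accessions,
#' both populations). A site is retained iff its missing-allele fraction is
#' at most \code{max_missing} and its minor allele frequency is at least
#' \code{min_maf}.
#'
#' @param panel a [VariantPanel-class]
#' @param max_missing maximum missing fraction (default 0.10)
#' @param min_maf minimum minor allele frequency (default 0.05)
#' @return the filtered [VariantPanel-class]
#' @export
filterVariants <- function(panel, max_missing = 0.10, min_maf = 0.05) {
  an <- panel@an; ac <- panel@ac
  n_tot <- 2L * ncol(an)
  called <- rowSums(an)
  miss <- 1 - called / n_tot
  p <- ifelse(called > 0, rowSums(ac) / called, NA_real_)
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf
  new("VariantPanel", chrom = panel@chrom[keep], pos = panel@pos[keep],
      ref = panel@ref[keep], alt = panel@alt[keep],
      ac = ac[keep, , drop = FALSE], an = an[keep, , drop = FALSE],
      populations = panel@populations)
}

#' Sliding windows along a chromosome
#'
#' Half-open windows \eqn{[k \cdot step, k \cdot step + size)} for
#' \eqn{k = 0, 1, \dots} while the start lies inside the chromosome; final
#' windows are truncated at the chromosome end. \code{size < step} is an
#' error (the tiling would skip positions).
#'
#' @param chrom_length chromosome length in bp
#' @param size window size (default 20000)
#' @param step window step (default 10000)
#' @return data.frame \code{start end} (0-based half-open)
#' @export
makeWindows <- function(chrom_length, size = 20000L, step = 10000L) {
  if (size < step) stop("size < step would leave gaps between windows")
  if (chrom_length <= 0) stop("chromosome length must be positive")
  starts <- seq.int(0L, chrom_length - 1L, by = step)
  data.frame(start = starts, end = pmin(starts + size, chrom_length))
}

# per-site unbiased heterozygosity for a set of accessions
.siteHet <- function(panel, acc_idx) {
  n <- rowSums(panel@an[, acc_idx, drop = FALSE])
  na_alt <- rowSums(panel@ac[, acc_idx, drop = FALSE])
  h <- numeric(length(n))
  ok <- n >= 2L
  p <- na_alt[ok] / n[ok]
  h[ok] <- n[ok] / (n[ok] - 1) * (1 - p^2 - (1 - p)^2)
  h
}

#' Windowed nucleotide diversity for one population
#'
#' Per site with \eqn{n} called alleles split \eqn{n_a / n_b}, the unbiased
#' heterozygosity \eqn{h = n/(n-1) (1 - (n_a/n)^2 - (n_b/n)^2)} is summed
#' over the sites inside each window and divided by the window span in bp
#' (truncated span for edge windows), so monomorphic positions count as zero
#' diversity. Sites with fewer than two called alleles are skipped.
#'
#' @param panel a [VariantPanel-class]
#' @param population population label selecting accessions
#' @param windows named list of window data.frames (one per chromosome, as
#'   from [makeWindows()]); names are chromosome ids
#' @return data.frame \code{chrom start end n_snps pi}
#' @export
windowPi <- function(panel, population, windows) {
  acc_idx <- which(panel@populations == population)
  if (!length(acc_idx)) stop("no accessions in population: ", population)
  h <- .siteHet(panel, acc_idx)
  out <- lapply(names(windows), function(ch) {
    w <- windows[[ch]]
    on_ch <- panel@chrom == ch
    q <- panel@pos[on_ch] - 1L  # 0-based site positions
    hv <- h[on_ch]
    span <- w$end - w$start
    sums <- numeric(nrow(w))
    cnts <- integer(nrow(w))
    if (length(q)) {
      step <- if (nrow(w) > 1L) w$start[2L] - w$start[1L] else w$end[1L]
      size <- max(span)
      kmax <- nrow(w) - 1L
      # a site belongs to at most ceiling(size/step) consecutive windows
      for (off in 0:(ceiling(size / step) - 1L)) {
        k <- q %/% step - off
        ok <- k >= 0L & k <= kmax
        if (!any(ok)) next
        kk <- k[ok]
        inside <- q[ok] < w$end[kk + 1L]
        if (any(inside)) {
          agg <- rowsum(hv[ok][inside], kk[inside])
          idx <- as.integer(rownames(agg)) + 1L
          sums[idx] <- sums[idx] + agg[, 1L]
          cnts[idx] <- cnts[idx] + rowsum(rep(1L, sum(inside)),
                                          kk[inside])[, 1L]
        }
      }
    }
    data.frame(chrom = ch, start = w$start, end = w$end,
               n_snps = cnts, pi = sums / span, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-window diversity ratio between populations
#'
#' Ratio \eqn{\pi_{cultivated} / \pi_{wild}} per window; windows with zero
#' wild diversity get an \code{NA} ratio and are excluded from any ranking.
#' Low ratios mark diversity lost in the cultivated population, i.e.
#' candidate selective sweeps.
#'
#' @param pi_wild,pi_cult window tables from [windowPi()] over the same
#'   window list
#' @return data.frame \code{chrom start end n_snps pi_wild pi_cult ratio}
#' @export
ratioScan <- function(pi_wild, pi_cult) {
  if (nrow(pi_wild) != nrow(pi_cult) ||
      !all(pi_wild$chrom == pi_cult$chrom & pi_wild$start == pi_cult$start &
           pi_wild$end == pi_cult$end))
    stop("window lists differ between populations")
  data.frame(
    chrom = pi_wild$chrom, start = pi_wild$start, end = pi_wild$end,
    n_snps = pi_wild$n_snps + pi_cult$n_snps,
    pi_wild = pi_wild$pi, pi_cult = pi_cult$pi,
    ratio = ifelse(pi_wild$pi > 0, pi_cult$pi / pi_wild$pi, NA_real_),
    stringsAsFactors = FALSE
  )
}

# windows overlapping each gene span (genes 1-based inclusive)
.geneWindowHits <- function(scan, genes) {
  gw <- GenomicRanges::GRanges(scan$chrom,
          IRanges::IRanges(scan$start + 1L, scan$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
          IRanges::IRanges(genes$start, genes$end))
  GenomicRanges::findOverlaps(gg, gw)
}

#' Chromosome-baseline comparison for gene regions
#'
#' The chromosome baseline is the arithmetic mean of the defined window
#' ratios on that chromosome; a gene's region ratio is the mean ratio of the
#' windows overlapping its span. The gene is flagged
#' \code{below_chromosome_mean} iff its region ratio is below the baseline
#' (diversity lost in excess of the chromosome average).
#'
#' @param scan window table from [ratioScan()]
#' @param genes data.frame \code{gene_id chrom start end} (1-based inclusive)
#' @return data.frame \code{gene_id chrom region_ratio chrom_mean
#'   below_chromosome_mean}
#' @export
chromosomeBaseline <- function(scan, genes) {
  cm <- tapply(scan$ratio, scan$chrom, mean, na.rm = TRUE)
  if (any(!genes$chrom %in% names(cm)) ||
      any(is.nan(cm[unique(genes$chrom)])))
    stop("gene on a chromosome with no defined windows")
  hits <- .geneWindowHits(scan, genes)
  rr <- rep(NA_real_, nrow(genes))
  agg <- tapply(scan$ratio[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), mean, na.rm = TRUE)
  rr[as.integer(names(agg))] <- agg
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    region_ratio = rr,
    chrom_mean = as.numeric(cm[genes$chrom]),
    below_chromosome_mean = !is.na(rr) & rr < as.numeric(cm[genes$chrom]),
    stringsAsFactors = FALSE
  )
}

#' Call selective sweeps from the lowest-ratio windows
#'
#' The sweep set is the lowest-\code{quantile} fraction of the defined
#' window ratios, genome-wide: the threshold is the largest ratio value
#' whose cumulative frequency does not exceed \code{quantile}, and every
#' window at or below it (ties included) is a sweep window. When even the
#' minimum ratio is more frequent than \code{quantile} (massive ties, e.g.
#' many zero-diversity windows) the minimum is used, so the selected
#' fraction can then exceed \code{quantile}. A gene is \code{top5_selected}
#' iff at least one overlapping window is a sweep window.
#'
#' @param scan window table from [ratioScan()]
#' @param genes data.frame \code{gene_id chrom start end}
#' @param quantile lower quantile defining sweep windows (default 0.05)
#' @return list with \code{threshold}, \code{windows} (the scan table plus a
#'   logical \code{sweep} column) and \code{genes} (data.frame
#'   \code{gene_id chrom top5_selected})
#' @export
callSweeps <- function(scan, genes, quantile = 0.05) {
  ratios <- scan$ratio[!is.na(scan$ratio)]
  if (length(ratios) < 20L)
    warning("fewer than 20 defined windows: quantile threshold is unstable")
  vals <- sort(unique(ratios))
  cumfrac <- vapply(vals, function(v) mean(ratios <= v), numeric(1))
  thr <- if (any(cumfrac <= quantile)) max(vals[cumfrac <= quantile])
         else vals[1L]
  sweep <- !is.na(scan$ratio) & scan$ratio <= thr
  hits <- .geneWindowHits(scan, genes)
  sel <- logical(nrow(genes))
  hit_sweep <- sweep[S4Vectors::subjectHits(hits)]
  sel[unique(S4Vectors::queryHits(hits)[hit_sweep])] <- TRUE
  list(threshold = thr,
       windows = cbind(scan, sweep = sweep),
       genes = data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                          top5_selected = sel, stringsAsFactors = FALSE))
}

#' Neighbor-joining tree of accessions from SNPs in gene regions
#'
#' Sites are restricted to the given gene regions; the distance between two
#' accessions is \eqn{1 - IBS}, the identity-by-state proportion over sites
#' where both are fully called. The tree is built with [njTree()].
#'
#' @param panel a [VariantPanel-class]
#' @param regions data.frame \code{chrom start end} (1-based inclusive)
#' @return an \code{ape::phylo} over the accessions
#' @export
accessionTree <- function(panel, regions) {
  keep <- rep(FALSE, length(panel@pos))
  for (i in seq_len(nrow(regions)))
    keep <- keep | (panel@chrom == regions$chrom[i] &
                    panel@pos >= regions$start[i] &
                    panel@pos <= regions$end[i])
  if (!any(keep)) stop("no sites inside the given regions")
  ac <- panel@ac[keep, , drop = FALSE]
  an <- panel@an[keep, , drop = FALSE]
  full <- an == 2L
  G <- ifelse(full, ac, 0L)        # dosage, 0 where not fully called
  M <- full * 1L
  GG <- crossprod(G)
  sq <- crossprod(G^2, M)
  nshared <- crossprod(M)
  d2 <- sq + t(sq) - 2 * GG        # sum over shared sites of (gi - gj)^2
  I0 <- (G == 0L & full) * 1L
  I2 <- (G == 2L) * 1L
  n2 <- crossprod(I0, I2)
  n2 <- n2 + t(n2)                 # sites with opposite homozygotes
  if (any(nshared == 0))
    stop("accession pair with no shared called sites")
  D <- (d2 - 2 * n2) / (2 * nshared)   # mean |gi - gj| / 2 = 1 - IBS
  dimnames(D) <- list(colnames(an), colnames(an))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  njTree(D)
}

#' Read gene regions from a BED file
#'
#' @param path BED path (0-based half-open on disk; converted to 1-based
#'   inclusive)
#' @return data.frame \code{gene_id chrom start end}
#' @export
readBedRegions <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 4L) stop("BED file needs at least 4 columns (chrom start end name)")
  data.frame(gene_id = b[[4L]], chrom = b[[1L]],
             start = b[[2L]] + 1L, end = b[[3L]], stringsAsFactors = FALSE)
}
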