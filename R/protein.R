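# Protein physico-chemical properties from the primary sequence.
# Average (not monoisotopic) residue masses; pI by bisection on net charge
# with the EMBOSS pKa set. pI values differ between published pKa tables
# (ExPASy/Bjellqvist vs EMBOSS), so only ranges are comparable across tools.

# average residue masses, Da (residue = amino acid minus water)
.AA_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

# EMBOSS pKa values
.PKA <- list(
  nterm = 8.6, cterm = 3.6,
  pos = c(K = 10.8, R = 12.5, H = 6.5),
  neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

.aaCounts <- function(peptide) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  aa <- aa[aa != "*"]
  bad <- setdiff(unique(aa), c(names(.AA_MASS), "X"))
  if (length(bad))
    stop("peptide contains non-standard residues: ", paste(bad, collapse = ", "))
  list(counts = table(factor(aa[aa != "X"], levels = names(.AA_MASS))),
       length = length(aa))
}

.netCharge <- function(counts, pH) {
  pos <- 1 / (1 + 10^(pH - .PKA$nterm)) +
    sum(counts[names(.PKA$pos)] / (1 + 10^(pH - .PKA$pos)))
  neg <- 1 / (1 + 10^(.PKA$cterm - pH)) +
    sum(counts[names(.PKA$neg)] / (1 + 10^(.PKA$neg - pH)))
  pos - neg
}

#' Peptide length, molecular weight and isoelectric point
#'
#' Molecular weight is the sum of average residue masses plus one water mass;
#' the isoelectric point is found by bisection on the net charge of the
#' Henderson-Hasselbalch model using the EMBOSS pKa set (free N/C termini,
#' charged side chains K, R, H, D, E, C, Y). \code{X} residues count toward
#' the length but are excluded from mass and charge.
#'
#' @param peptide amino-acid string over the 20-letter alphabet (X allowed; a
#'   trailing \code{*} is ignored)
#' @param tol bisection stops when |net charge| < \code{tol}
#' @return list with \code{length_aa}, \code{mw_da}, \code{pi}
#' @examples
#' proteinProperties("ACDE")$length_aa  # 4
#' proteinProperties("G")$mw_da         # 75.0672
#' @export
proteinProperties <- function(peptide, tol = 1e-4) {
  if (!is.character(peptide) || length(peptide) != 1L || nchar(peptide) == 0L ||
      identical(peptide, "*"))
    stop("peptide must be a single non-empty string")
  info <- .aaCounts(peptide)
  counts <- info$counts
  mw <- sum(counts * .AA_MASS[names(counts)]) + .WATER_MASS
  lo <- 0; hi <- 14
  pi <- NA_real_
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- .netCharge(counts, mid)
    if (abs(q) < tol) { pi <- mid; break }
    if (q > 0) lo <- mid else hi <- mid
  }
  if (is.na(pi)) pi <- (lo + hi) / 2
  list(length_aa = info$length, mw_da = unname(mw), pi = pi)
}
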