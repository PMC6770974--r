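# Expression-pattern classification from FPKM matrices: constitutive high
# expression against the grand mean, tissue specificity by the tau index,
# inactivity, infection-response time courses, collinear-pair divergence and
# qPCR relative expression.

#' Read an FPKM matrix (genes in rows, samples in columns)
#'
#' First column holds gene ids; the header row holds sample labels.
#'
#' @param path TSV path
#' @return numeric matrix with gene rownames
#' @export
readFpkm <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1L]]
  if (anyDuplicated(colnames(m))) stop("duplicated sample labels")
  if (any(m < 0, na.rm = TRUE)) stop("negative FPKM values")
  m
}

#' Highly / constitutively expressed genes
#'
#' A gene is called \code{high} iff its across-sample mean is at least
#' \code{fold} times the grand mean of the whole matrix (every gene x sample
#' entry). With an all-zero matrix every gene is \code{not_high}, with a
#' warning.
#'
#' @param mat FPKM matrix, genes x samples
#' @param fold fold-change over the grand mean (default 3)
#' @param grand_mean optionally override the grand mean (e.g. the genome-wide
#'   value when \code{mat} is a subset of genes)
#' @return named character vector, \code{"high"}/\code{"not_high"} per gene
#' @export
classifyHigh <- function(mat, fold = 3, grand_mean = NULL) {
  if (!length(mat)) stop("empty matrix")
  m <- if (is.null(grand_mean)) mean(mat) else grand_mean
  if (m == 0) {
    warning("grand mean is zero: all genes reported not_high")
    return(stats::setNames(rep("not_high", nrow(mat)), rownames(mat)))
  }
  lab <- ifelse(rowMeans(mat) >= fold * m, "high", "not_high")
  stats::setNames(lab, rownames(mat))
}

#' Tissue specificity by the tau index
#'
#' \eqn{\tau = \sum_i (1 - x_i / x_{max}) / (n - 1)} over the expression row;
#' \eqn{\tau = 1} for expression confined to a single tissue, 0 for a
#' uniform row. A gene is called \code{specific} iff \eqn{\tau \ge}
#' \code{tau_min} and its maximum FPKM is at least \code{min_max_fpkm}
#' (guards against calling specificity on noise-level rows). An all-zero row
#' has undefined tau and is labelled \code{inactive}.
#'
#' @param row nonnegative numeric vector (>= 2 samples), names = tissues
#' @param tau_min specificity cutoff on tau (default 0.85)
#' @param min_max_fpkm floor on the peak FPKM (default 10)
#' @return list with \code{tau}, \code{tissue} (argmax sample) and
#'   \code{label} in \code{specific}/\code{broad}/\code{inactive}
#' @export
tissueSpecificity <- function(row, tau_min = 0.85, min_max_fpkm = 10) {
  if (length(row) < 2L) stop("need at least 2 samples")
  if (any(row < 0)) stop("negative FPKM")
  mx <- max(row)
  if (mx == 0)
    return(list(tau = NA_real_, tissue = NA_character_, label = "inactive"))
  tau <- sum(1 - row / mx) / (length(row) - 1L)
  top <- if (!is.null(names(row))) names(row)[which.max(row)]
         else as.character(which.max(row))
  label <- if (tau >= tau_min && mx >= min_max_fpkm) "specific" else "broad"
  list(tau = tau, tissue = top, label = label)
}

#' Inactive genes (below an FPKM floor everywhere)
#'
#' @param row numeric expression vector
#' @param floor_fpkm inactivity floor (default 1 FPKM); a sample at exactly
#'   the floor makes the gene active
#' @return \code{"inactive"} or \code{"active"}
#' @export
classifyInactive <- function(row, floor_fpkm = 1) {
  if (all(row < floor_fpkm)) "inactive" else "active"
}

#' Infection-response classification from a time course
#'
#' Per time point \eqn{L_t = \log_2((FPKM_t + 0.001) / (FPKM_0 + 0.001))}
#' against the 0 h baseline. A gene is \code{induced} iff
#' \eqn{\max L_t \ge} \code{up_thresh} and \eqn{\min L_t >} \code{down_thresh};
#' \code{suppressed} symmetrically; both thresholds exceeded gives
#' \code{mixed}, neither \code{unchanged}. Genes whose FPKM never reaches
#' \code{min_peak_fpkm} are \code{unchanged} regardless (pseudocount-noise
#' guard).
#'
#' @param timecourse numeric vector, first element the 0 h baseline; names
#'   are time labels
#' @param up_thresh,down_thresh log2 thresholds (defaults +1 / -1)
#' @param min_peak_fpkm peak-FPKM floor (default 0.5)
#' @return list with \code{l2fc} (per post-baseline time point) and
#'   \code{category} in \code{induced}/\code{suppressed}/\code{mixed}/
#'   \code{unchanged}
#' @export
infectionResponse <- function(timecourse, up_thresh = 1, down_thresh = -1,
                              min_peak_fpkm = 0.5) {
  if (length(timecourse) < 2L) stop("time course needs a 0 h baseline and at least one later point")
  base <- timecourse[[1L]]
  later <- timecourse[-1L]
  l2 <- log2((later + 0.001) / (base + 0.001))
  # small tolerance so an exact k-fold change is not pushed just under the
  # threshold by the 0.001 pseudocount
  tol <- 1e-3
  up <- max(l2) >= up_thresh - tol
  down <- min(l2) <= down_thresh + tol
  category <- if (max(timecourse) < min_peak_fpkm) "unchanged"
    else if (up && down) "mixed"
    else if (up) "induced"
    else if (down) "suppressed"
    else "unchanged"
  list(l2fc = l2, category = category)
}

#' Relative expression by the 2^-ddCt method
#'
#' \eqn{\Delta\Delta Ct = (Ct_{target,treated} - Ct_{ref,treated}) -
#' (Ct_{target,control} - Ct_{ref,control})}; fold change \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (positive)
#' @return fold change relative to the control condition
#' @examples
#' ddCt(20, 18, 22, 19)  # ddCt = -1, fold 2
#' @export
ddCt <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  stopifnot(ct_target_treated > 0, ct_ref_treated > 0,
            ct_target_control > 0, ct_ref_control > 0)
  dd <- (ct_target_treated - ct_ref_treated) -
        (ct_target_control - ct_ref_control)
  2^(-dd)
}

#' Expression divergence of a collinear gene pair
#'
#' Pearson correlation of \eqn{\log_2(FPKM + 1)} across the shared samples;
#' the pair is \code{similar} iff \eqn{r \ge} \code{r_thresh}. A constant row
#' has no defined correlation: the pair is \code{distinct} unless both rows
#' are constant and equal.
#'
#' @param row_a,row_b expression vectors over the same samples (>= 3)
#' @param r_thresh correlation threshold (default 0.5)
#' @return list with \code{r} (possibly \code{NA}) and \code{label}
#' @export
pairDivergence <- function(row_a, row_b, r_thresh = 0.5) {
  if (length(row_a) != length(row_b)) stop("rows must share the sample set")
  if (length(row_a) < 3L) stop("need at least 3 samples")
  la <- log2(row_a + 1); lb <- log2(row_b + 1)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    lab <- if (stats::sd(la) == 0 && stats::sd(lb) == 0 &&
               isTRUE(all.equal(la, lb))) "similar" else "distinct"
    return(list(r = NA_real_, label = lab))
  }
  r <- stats::cor(la, lb)
  list(r = r, label = if (r >= r_thresh) "similar" else "distinct")
}

#' Summary of pair-divergence labels
#'
#' @param labels character vector of \code{similar}/\code{distinct} labels
#' @return list with counts and the percentage (one decimal) of distinct
#'   pairs
#' @export
summarizePairDivergence <- function(labels) {
  n <- length(labels)
  nd <- sum(labels == "distinct")
  list(n_pairs = n, n_distinct = nd, n_similar = n - nd,
       distinct_pct = if (n) round(100 * nd / n, 1) else 0)
}
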