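# Nei-Gojobori (1986) Ka/Ks with equal pathway weighting and Jukes-Cantor
# correction. Site counting excludes single-nucleotide changes that create a
# stop codon (from both numerator and denominator); mutational pathways that
# pass through a stop codon are discarded, and only if every pathway between
# a codon pair is discarded are all pathways used with stop-crossing steps
# counted as nonsynonymous (a rare, documented fallback).

.kaksCache <- new.env(parent = emptyenv())

.codonTables <- function() {
  if (!is.null(.kaksCache$ready)) return(invisible(NULL))
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(nts, nts, paste0), nts,
                            function(ab, c) paste0(ab, c)))
  codons <- sort(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  is_stop <- aa == "*"

  # per-codon synonymous site count
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  for (c0 in codons[!is_stop]) {
    s <- 0
    for (p in 1:3) {
      alts <- vapply(setdiff(nts, substr(c0, p, p)), function(nt) {
        x <- c0; substr(x, p, p) <- nt; x
      }, character(1))
      alts <- alts[!is_stop[alts]]
      if (length(alts))
        s <- s + sum(aa[alts] == aa[c0]) / length(alts)
    }
    syn_sites[c0] <- s
  }

  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sense <- codons[!is_stop]
  n <- length(codons)
  sd <- matrix(0, n, n, dimnames = list(codons, codons))
  nd <- sd
  for (a in sense) for (b in sense) {
    if (a >= b) next
    pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
    if (!length(pos)) next
    pm <- perms[[as.character(length(pos))]]
    paths <- apply(pm, 1L, function(ord) {
      cur <- a
      steps_syn <- 0; steps_non <- 0; through_stop <- FALSE
      for (p in pos[ord]) {
        nxt <- cur
        substr(nxt, p, p) <- substr(b, p, p)
        if (is_stop[nxt]) through_stop <- TRUE
        if (!is_stop[cur] && !is_stop[nxt] && aa[cur] == aa[nxt])
          steps_syn <- steps_syn + 1
        else
          steps_non <- steps_non + 1
        cur <- nxt
      }
      c(steps_syn, steps_non, through_stop)
    })
    valid <- paths[3L, ] == 0
    use <- if (any(valid)) paths[, valid, drop = FALSE] else paths
    sd[a, b] <- sd[b, a] <- mean(use[1L, ])
    nd[a, b] <- nd[b, a] <- mean(use[2L, ])
  }
  .kaksCache$aa <- aa
  .kaksCache$is_stop <- is_stop
  .kaksCache$syn_sites <- syn_sites
  .kaksCache$sd <- sd
  .kaksCache$nd <- nd
  .kaksCache$ready <- TRUE
  invisible(NULL)
}

.splitCodons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(x, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

.jcCorrect <- function(p, rate) {
  if (p >= 0.75) {
    warning(sprintf("%s saturated (p = %.4f >= 3/4): Jukes-Cantor distance is infinite",
                    rate, p))
    return(Inf)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' Synonymous/nonsynonymous site counts are computed per codon and averaged
#' over the two sequences; observed differences are counted by averaging over
#' all minimal mutational pathways between differing codons with equal
#' weights. The proportions are corrected for multiple hits with the
#' Jukes-Cantor formula \eqn{d = -3/4 \ln(1 - 4p/3)}. A saturated rate
#' (\eqn{p \ge 3/4}) is reported as \code{Inf} with a warning.
#'
#' @param cds_a,cds_b equal-length, in-frame codon-aligned nucleotide
#'   strings; codon pairs containing gaps, ambiguity characters or stop
#'   codons in either sequence are skipped
#' @return list with \code{ka}, \code{ks}, \code{omega} (\code{NA} when Ks is
#'   zero), raw counts \code{sd}, \code{nd}, site counts \code{s_sites},
#'   \code{n_sites} and \code{n_codons} used
#' @examples
#' r <- ng86KaKs("TTTGGGAAACCC", "TTTGGGAAACCC")
#' r$ka; r$ks          # both 0, omega NA
#' @export
ng86KaKs <- function(cds_a, cds_b) {
  .codonTables()
  if (nchar(cds_a) != nchar(cds_b))
    stop("sequences must be equal length (codon-aligned)")
  ca <- .splitCodons(cds_a)
  cb <- .splitCodons(cds_b)
  known <- names(.kaksCache$aa)
  usable <- ca %in% known & cb %in% known &
    !.kaksCache$is_stop[ca] & !.kaksCache$is_stop[cb]
  usable[is.na(usable)] <- FALSE
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) stop("no usable codons")
  s_a <- sum(.kaksCache$syn_sites[ca])
  s_b <- sum(.kaksCache$syn_sites[cb])
  s_sites <- (s_a + s_b) / 2
  n_sites <- 3 * length(ca) - s_sites
  sd <- sum(.kaksCache$sd[cbind(ca, cb)])
  nd <- sum(.kaksCache$nd[cbind(ca, cb)])
  ks <- .jcCorrect(sd / s_sites, "Ks")
  ka <- .jcCorrect(nd / n_sites, "Ka")
  omega <- if (ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, omega = omega, sd = sd, nd = nd,
       s_sites = s_sites, n_sites = n_sites, n_codons = length(ca))
}
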