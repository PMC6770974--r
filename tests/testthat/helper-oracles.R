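# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (enumeration, explicit pairwise sums) and
# share no code with the implementation they check.

# --- NG86 pathway oracle -----------------------------------------------------

.oracle_gc <- as.list(Biostrings::GENETIC_CODE)

oracle_sense_codons <- function() {
  nts <- c("A", "C", "G", "T")
  all <- apply(expand.grid(nts, nts, nts), 1L, paste, collapse = "")
  sort(all[unlist(.oracle_gc[all]) != "*"])
}

# per-codon synonymous site count: per position, fraction of non-stop
# single-nucleotide changes that preserve the amino acid
oracle_syn_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    neigh <- vapply(setdiff(nts, substr(codon, p, p)), function(nt) {
      x <- codon; substr(x, p, p) <- nt; x
    }, character(1))
    neigh <- neigh[unlist(.oracle_gc[neigh]) != "*"]
    if (length(neigh))
      s <- s + sum(unlist(.oracle_gc[neigh]) == .oracle_gc[[codon]]) /
        length(neigh)
  }
  s
}

# average synonymous/nonsynonymous step counts over all orderings of the
# differing positions; orderings passing through a stop are dropped (all
# orderings used, stop steps nonsynonymous, if none survive)
oracle_path_counts <- function(a, b) {
  pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  walk <- function(ord) {
    cur <- a; sd <- 0; nd <- 0; stopped <- FALSE
    for (p in ord) {
      nxt <- cur; substr(nxt, p, p) <- substr(b, p, p)
      if (.oracle_gc[[nxt]] == "*") stopped <- TRUE
      if (.oracle_gc[[cur]] != "*" && .oracle_gc[[nxt]] != "*" &&
          .oracle_gc[[cur]] == .oracle_gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, stopped)
  }
  res <- vapply(perms(pos), walk, numeric(3))
  ok <- res[3L, ] == 0
  use <- if (any(ok)) res[, ok, drop = FALSE] else res
  c(sd = mean(use[1L, ]), nd = mean(use[2L, ]))
}

# --- pairwise-difference pi oracle ------------------------------------------

# explicit average pairwise differences among called alleles, summed over
# sites and divided by the span
oracle_window_pi <- function(ac, an, span) {
  total <- 0
  for (s in seq_len(nrow(ac))) {
    alleles <- integer(0)
    for (j in seq_len(ncol(ac))) {
      n <- an[s, j]; a <- ac[s, j]
      alleles <- c(alleles, rep(1L, a), rep(0L, n - a))
    }
    n <- length(alleles)
    if (n < 2L) next
    diffs <- 0
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n) diffs <- diffs + (alleles[i] != alleles[j])
    total <- total + diffs / choose(n, 2L)
  }
  total / span
}

# --- longest monotone chain oracle ------------------------------------------

# exhaustive search over anchor subsets (n <= 15): maximum summed weight of
# a chain of >= min_len anchors, strictly monotone in both ranks with
# consecutive gaps <= max_gap; 0 when no such chain exists
oracle_best_chain <- function(ra, rb, w, max_gap, min_len = 2L) {
  n <- length(ra)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < min_len) next
    idx <- idx[order(ra[idx], rb[idx])]
    da <- diff(ra[idx]); db <- diff(rb[idx])
    okf <- all(da >= 1 & da <= max_gap) && all(db >= 1 & db <= max_gap)
    okr <- all(da >= 1 & da <= max_gap) && all(-db >= 1 & -db <= max_gap)
    if (okf || okr) best <- max(best, sum(w[idx]))
  }
  best
}

# --- random additive trees ---------------------------------------------------

random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
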