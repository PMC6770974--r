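# Distance-based phylogeny: p-distances from an existing peptide alignment,
# neighbor-joining with deterministic tie-breaking, column bootstrap, and
# reference-anchored clade classification.

#' Read an aligned FASTA into a character matrix
#'
#' @param path aligned FASTA (equal-length gapped sequences, gap \code{-})
#' @return character matrix, taxa x sites, rownames = taxa ids
#' @export
readAlignedFasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  names(s) <- sub("\\s.*$", "", names(s))
  if (length(unique(Biostrings::width(s))) != 1L)
    stop("alignment rows differ in length")
  alignmentMatrix(stats::setNames(as.character(s), names(s)))
}

#' @rdname readAlignedFasta
#' @param seqs named character vector of equal-length gapped sequences
#' @export
alignmentMatrix <- function(seqs) {
  if (length(seqs) < 2L) stop("alignment needs at least 2 taxa")
  n <- unique(nchar(seqs))
  if (length(n) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Pairwise distances from an alignment
#'
#' Uncorrected p-distance (mismatches over compared sites), optionally with
#' the Poisson correction \eqn{d = -\ln(1 - p)}. Under
#' \code{complete_deletion} only columns with no gap in any row are compared
#' (the "conserved sites" of a typical family alignment); under
#' \code{pairwise_deletion} each pair uses the columns where both rows are
#' ungapped.
#'
#' @param aln taxa x sites character matrix (see [alignmentMatrix()])
#' @param site_policy \code{"complete_deletion"} (default) or
#'   \code{"pairwise_deletion"}
#' @param model \code{"p"} (default) or \code{"poisson"}
#' @return symmetric distance matrix with zero diagonal
#' @export
pDistance <- function(aln, site_policy = c("complete_deletion",
                                           "pairwise_deletion"),
                      model = c("p", "poisson")) {
  site_policy <- match.arg(site_policy)
  model <- match.arg(model)
  if (nrow(aln) < 2L) stop("alignment needs at least 2 taxa")
  gap <- aln == "-"
  if (site_policy == "complete_deletion") {
    keep <- colSums(gap) == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion")
    aln <- aln[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(aln)
  # mismatches via indicator cross-products: compared(i,j) = ungapped both,
  # matches(i,j) = sum over residues of co-occurrence counts
  ok <- (!gap) * 1
  compared <- tcrossprod(ok)
  matches <- matrix(0, n, n)
  for (a in setdiff(unique(as.vector(aln)), "-"))
    matches <- matches + tcrossprod((aln == a) * 1)
  off <- compared == 0 & !diag(n)
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero comparable sites between %s and %s",
                 rownames(aln)[ij[1L]], rownames(aln)[ij[2L]]))
  }
  D <- (compared - matches) / pmax(compared, 1)
  diag(D) <- 0
  dimnames(D) <- list(rownames(aln), rownames(aln))
  if (model == "poisson") {
    if (any(D >= 1)) stop("p-distance of 1: Poisson correction undefined")
    D <- -log(1 - D)
    diag(D) <- 0
  }
  D
}

.checkDistanceMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix needs taxon names")
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  invisible(TRUE)
}

#' Neighbor-joining tree with deterministic tie-breaking
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion. At every step the
#' pair minimizing Q is joined; ties (within 1e-12) are broken by the
#' lexicographically smallest pair of cluster labels, a cluster being
#' labelled by its smallest member taxon. Negative branch lengths are clamped
#' to zero with the deficit transferred to the sibling edge, so path lengths
#' are preserved. On an additive input matrix the tree's path-length matrix
#' reproduces the input exactly.
#'
#' @param D symmetric nonnegative distance matrix with taxon dimnames
#' @return an unrooted \code{ape::phylo} (basal trifurcation)
#' @export
njTree <- function(D) {
  .checkDistanceMatrix(D)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  # newick fragment and lexicographic cluster key per active node
  frag <- labels
  key <- labels
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(pk)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nm <- c(rownames(D)[keep], newkey)
    dimnames(D2) <- list(nm, nm)
    D <- D2
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  # final star: three-point formulas
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0)
  ord <- order(key)
  fr <- frag[ord]; ln <- c(l1, l2, l3)[ord]
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 fr[1], fmt(ln[1]), fr[2], fmt(ln[2]), fr[3], fmt(ln[3]))
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' replicate with [pDistance()] + [njTree()], and reports for each internal
#' edge of the full-data tree the percentage of replicates containing the
#' same bipartition (unrooted comparison via \code{ape::prop.clades}).
#' Deterministic for a given seed; resampling depends on columns only, so
#' supports are invariant under taxon reordering.
#'
#' @param aln taxa x sites character matrix
#' @param n_reps number of bootstrap replicates (>= 1)
#' @param seed mandatory integer seed
#' @param site_policy,model passed to [pDistance()]; resampling draws from
#'   the columns the policy admits for the full alignment
#' @return list with \code{tree} (the full-data \code{phylo}, node labels set
#'   to integer supports in 0..100) and \code{support} (numeric vector per
#'   internal node)
#' @export
bootstrapPhylo <- function(aln, n_reps, seed,
                           site_policy = "complete_deletion", model = "p") {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_reps >= 1L)
  if (site_policy == "complete_deletion") {
    aln <- aln[, colSums(aln == "-") == 0L, drop = FALSE]
    site_policy <- "pairwise_deletion"  # already gap-free; avoids re-filtering
  }
  main <- njTree(pDistance(aln, site_policy, model))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(aln), replace = TRUE)
    reps[[b]] <- njTree(pDistance(aln[, idx, drop = FALSE],
                                  site_policy, model))
  }
  class(reps) <- "multiPhylo"
  cnt <- ape::prop.clades(main, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  support <- round(100 * cnt / n_reps)
  main$node.label <- as.character(support)
  list(tree = main, support = support)
}

#' Assign family members to classes anchored on reference leaves
#'
#' The tree is midpoint-rooted (longest leaf-to-leaf path) and each unlabeled
#' leaf receives class C iff the smallest clade containing that leaf and at
#' least one reference contains references of class C only; if that clade
#' mixes reference classes the leaf is \code{"unresolved"}.
#'
#' @param tree an \code{ape::phylo}
#' @param reference_labels named character vector mapping reference leaf ids
#'   to class labels
#' @return named character vector: class per non-reference leaf
#' @export
assignClasses <- function(tree, reference_labels) {
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (!length(refs)) stop("no reference leaves present in tree")
  rooted <- phangorn::midpoint(tree)
  tips <- rooted$tip.label
  ref_idx <- match(refs, tips)
  query <- setdiff(tips, refs)
  anc <- phangorn::Ancestors(rooted, seq_along(tips), type = "all")
  res <- stats::setNames(character(length(query)), query)
  for (q in query) {
    qi <- match(q, tips)
    found <- "unresolved"
    for (node in anc[[qi]]) {
      dtips <- phangorn::Descendants(rooted, node, type = "tips")[[1L]]
      inref <- intersect(dtips, ref_idx)
      if (length(inref)) {
        cls <- unique(reference_labels[tips[inref]])
        found <- if (length(cls) == 1L) unname(cls) else "unresolved"
        break
      }
    }
    res[q] <- found
  }
  res
}

#' Write a tree in Newick format
#'
#' @param tree \code{ape::phylo} (node labels, e.g. bootstrap supports, are
#'   preserved)
#' @param path output path
#' @export
writeTree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
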