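# Collinearity (synteny-block) detection by rank-based chain DP,
# tandem/segmental duplication typing, WGD-event binning and molecular
# dating.

#' Read all-vs-all homology hits / genome gene order
#'
#' \code{readHomologHits}: TSV with header \code{query subject evalue
#' bitscore}. \code{readGeneOrder}: TSV with header \code{gene_id chromosome
#' rank}, giving every gene's rank along its chromosome (family and
#' non-family genes alike).
#'
#' @param path TSV path
#' @return data.frame
#' @export
readHomologHits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query", "subject", "evalue", "bitscore")
  if (!all(need %in% names(h)))
    stop("homolog table must have columns: ", paste(need, collapse = ", "))
  if (any(h$evalue < 0)) stop("negative E-value in homolog table")
  h
}

#' @rdname readHomologHits
#' @export
readGeneOrder <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "rank")
  if (!all(need %in% names(g)))
    stop("gene-order table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("duplicated gene ids in gene order")
  g
}

# maximum-weight monotone chain of >= min_len anchors by layered DP;
# anchors: data.frame ra, rb, w (pre-sorted by ra then rb); direction +1
# (rb increasing) or -1 (rb decreasing). Layer l < min_len holds chains of
# exactly l anchors, layer min_len holds chains of >= min_len.
.bestChain <- function(anchors, max_gap, direction, min_len) {
  n <- nrow(anchors)
  ra <- anchors$ra; rb <- anchors$rb * direction; w <- anchors$w
  m <- max(1L, min_len)
  W <- matrix(-Inf, n, m)
  P <- matrix(NA_integer_, n, m)  # encodes (predecessor index, layer)
  W[, 1L] <- w
  if (m > 1L) for (j in seq_len(n)) {
    p <- seq_len(j - 1L)
    if (j == 1L) next
    ok <- p[ra[p] < ra[j] & ra[j] - ra[p] <= max_gap &
            rb[p] < rb[j] & rb[j] - rb[p] <= max_gap]
    if (!length(ok)) next
    for (l in 2:m) {
      cand <- W[ok, l - 1L]
      lvl <- rep(l - 1L, length(ok))
      if (l == m) {  # chains may grow beyond min_len within the top layer
        longer <- W[ok, m] > cand
        cand[longer] <- W[ok, m][longer]
        lvl[longer] <- m
      }
      k <- which.max(cand)
      if (is.finite(cand[k]) && w[j] + cand[k] > W[j, l]) {
        W[j, l] <- w[j] + cand[k]
        P[j, l] <- ok[k] + n * (lvl[k] - 1L)
      }
    }
  }
  end <- which.max(W[, m])
  if (!is.finite(W[end, m])) return(list(idx = integer(0), weight = -Inf))
  chain <- integer(0)
  j <- end; l <- m
  repeat {
    chain <- c(j, chain)
    enc <- P[j, l]
    if (is.na(enc)) break
    j <- (enc - 1L) %% n + 1L
    l <- (enc - 1L) %/% n + 1L
  }
  list(idx = chain, weight = W[end, m])
}

#' Detect collinear (synteny) blocks from homology hits
#'
#' Within each chromosome pair, anchors (hits passing the E-value cutoff) are
#' chained by a maximum-weight strictly monotone chain (dynamic programming
#' on gene ranks; weight = summed bit score), allowing rank gaps of at most
#' \code{max_rank_gap} in both genomes. Chains in both orientations (B-ranks
#' increasing or decreasing) are considered; when chains could share anchors
#' the higher-scoring chain wins, the block is removed, and remaining anchors
#' may form further chains. Maximal chains with at least \code{min_anchors}
#' anchors are reported; every hit belongs to at most one block.
#'
#' @param hits data.frame as from [readHomologHits()]
#' @param gene_order data.frame as from [readGeneOrder()]
#' @param min_anchors minimum anchors per block (default 5, the usual
#'   collinearity-tool setting)
#' @param max_rank_gap maximum rank difference between consecutive anchors
#'   (default 25)
#' @param evalue_max hit E-value cutoff (default 1e-5)
#' @return list of blocks; each block is a list with \code{chrom_a},
#'   \code{chrom_b}, \code{orientation} (\code{"same"}/\code{"inverted"}) and
#'   \code{anchors}, a data.frame \code{gene_a gene_b rank_a rank_b bitscore}
#'   with ranks strictly monotone
#' @export
detectBlocks <- function(hits, gene_order, min_anchors = 5L,
                         max_rank_gap = 25L, evalue_max = 1e-5) {
  hits <- hits[hits$evalue <= evalue_max & hits$query != hits$subject, ,
               drop = FALSE]
  if (!nrow(hits)) return(list())
  missing <- setdiff(unique(c(hits$query, hits$subject)), gene_order$gene_id)
  if (length(missing))
    stop("genes in hits missing from gene order: ",
         paste(missing, collapse = ", "))
  chrom <- stats::setNames(gene_order$chromosome, gene_order$gene_id)
  rank <- stats::setNames(gene_order$rank, gene_order$gene_id)

  cq <- chrom[hits$query]; cs <- chrom[hits$subject]
  rq <- rank[hits$query]; rs <- rank[hits$subject]
  swap <- cq > cs | (cq == cs & rq > rs)
  a <- data.frame(
    gene_a = ifelse(swap, hits$subject, hits$query),
    gene_b = ifelse(swap, hits$query, hits$subject),
    chrom_a = ifelse(swap, cs, cq), chrom_b = ifelse(swap, cq, cs),
    ra = ifelse(swap, rs, rq), rb = ifelse(swap, rq, rs),
    w = hits$bitscore, stringsAsFactors = FALSE
  )
  # dedup mirrored / repeated anchors, best score kept
  a <- a[order(a$chrom_a, a$chrom_b, a$ra, a$rb, -a$w), , drop = FALSE]
  a <- a[!duplicated(a[, c("chrom_a", "chrom_b", "ra", "rb")]), , drop = FALSE]

  blocks <- list()
  for (grp in split(a, paste(a$chrom_a, a$chrom_b, sep = "\r"))) {
    pool <- grp[order(grp$ra, grp$rb), , drop = FALSE]
    repeat {
      if (nrow(pool) < min_anchors) break
      fwd <- .bestChain(pool, max_rank_gap, +1L, min_anchors)
      rev <- .bestChain(pool, max_rank_gap, -1L, min_anchors)
      use <- if (rev$weight > fwd$weight) list(rev, "inverted")
             else list(fwd, "same")
      idx <- use[[1L]]$idx
      if (length(idx) < min_anchors) break
      anc <- pool[idx, c("gene_a", "gene_b", "ra", "rb", "w")]
      names(anc) <- c("gene_a", "gene_b", "rank_a", "rank_b", "bitscore")
      rownames(anc) <- NULL
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = pool$chrom_a[1L], chrom_b = pool$chrom_b[1L],
        orientation = use[[2L]], anchors = anc)
      pool <- pool[-idx, , drop = FALSE]
    }
  }
  blocks
}

#' Tandem duplication by adjacency on the chromosome
#'
#' Two family members are tandem-linked iff they lie on the same chromosome
#' with at most one non-family gene between them; the tandem set is the union
#' of all linked clusters of size >= 2. Depends only on gene order and family
#' membership, not on gene names.
#'
#' @param gene_order data.frame as from [readGeneOrder()] (full genome order)
#' @param family_members character vector of family gene ids
#' @return character vector: family members classified as tandem duplicates
#' @export
classifyTandem <- function(gene_order, family_members) {
  fam <- gene_order[gene_order$gene_id %in% family_members, , drop = FALSE]
  out <- character(0)
  for (grp in split(fam, fam$chromosome)) {
    grp <- grp[order(grp$rank), , drop = FALSE]
    if (nrow(grp) < 2L) next
    linked <- diff(grp$rank) <= 2L  # <= 1 intervening gene
    cl <- cumsum(c(TRUE, !linked))
    for (ids in split(grp$gene_id, cl))
      if (length(ids) >= 2L) out <- c(out, ids)
  }
  sort(unique(out))
}

#' Segmental duplication from synteny blocks
#'
#' A family member is segmental iff it is an anchor in at least one block
#' whose matched anchor is also a family member; the collinear family pairs
#' are those matched anchor pairs with both genes in the family.
#'
#' @param blocks block list from [detectBlocks()]
#' @param family_members character vector of family gene ids
#' @return list with \code{segmental} (character vector of members) and
#'   \code{pairs} (data.frame \code{gene_a gene_b}, unique, with
#'   \code{gene_a < gene_b})
#' @export
classifySegmental <- function(blocks, family_members) {
  pairs <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  for (b in blocks) {
    anc <- b$anchors
    both <- anc$gene_a %in% family_members & anc$gene_b %in% family_members
    if (any(both)) {
      p <- anc[both, c("gene_a", "gene_b")]
      flip <- p$gene_a > p$gene_b
      tmp <- p$gene_a[flip]; p$gene_a[flip] <- p$gene_b[flip]
      p$gene_b[flip] <- tmp
      pairs <- rbind(pairs, p)
    }
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(segmental = sort(unique(c(pairs$gene_a, pairs$gene_b))), pairs = pairs)
}

#' Assign a duplicate pair to a whole-genome-duplication event by Ks
#'
#' Half-open bins, the boundary belonging to the older event:
#' \eqn{[0, 0.3)} Glycine-genus WGD, \eqn{[0.3, 1.5)} legume WGD,
#' \eqn{\ge 1.5} gamma WGD.
#'
#' @param ks numeric vector of synonymous divergences (>= 0)
#' @return factor with levels \code{glycine}, \code{legume}, \code{gamma}
#' @export
assignWgdBin <- function(ks) {
  if (any(ks < 0, na.rm = TRUE)) stop("negative Ks")
  cut(ks, breaks = c(0, 0.3, 1.5, Inf), right = FALSE,
      labels = c("glycine", "legume", "gamma"))
}

#' Date a duplication event from Ks under a molecular clock
#'
#' \eqn{T = Ks / (2\lambda)}, reported in million years (Mya); the default
#' clock rate is 6.1e-9 synonymous substitutions per site per year, the
#' value commonly used for legumes.
#'
#' @param ks synonymous divergence (substitutions per synonymous site)
#' @param lambda_rate substitutions per site per year (> 0)
#' @return divergence time in Mya
#' @examples
#' dateDuplication(0.122)  # 10 Mya
#' @export
dateDuplication <- function(ks, lambda_rate = 6.1e-9) {
  if (lambda_rate <= 0) stop("lambda_rate must be positive")
  if (any(ks < 0, na.rm = TRUE)) stop("negative Ks")
  ks / (2 * lambda_rate) / 1e6
}

#' Summarize duplication classes of a gene family
#'
#' Per-WGD-bin counts and percentages (one decimal) of the collinear pairs,
#' plus tandem and segmental membership as percentages of family size.
#'
#' @param wgd_bins factor/character vector, one WGD bin per collinear pair
#'   (as from [assignWgdBin()])
#' @param n_tandem number of tandem family members
#' @param n_segmental number of segmental family members
#' @param family_size total family size
#' @return list with \code{bins} (data.frame \code{bin n pct}),
#'   \code{n_pairs}, \code{tandem_pct}, \code{segmental_pct}
#' @export
summarizeDuplication <- function(wgd_bins, n_tandem, n_segmental,
                                 family_size) {
  bins <- factor(wgd_bins, levels = c("glycine", "legume", "gamma"))
  n <- length(bins)
  cnt <- table(bins)
  pct <- if (n) round(100 * as.integer(cnt) / n, 1) else rep(0, 3L)
  list(
    bins = data.frame(bin = names(cnt), n = as.integer(cnt), pct = pct,
                      stringsAsFactors = FALSE),
    n_pairs = n,
    tandem_pct = if (family_size) round(100 * n_tandem / family_size, 1) else 0,
    segmental_pct = if (family_size) round(100 * n_segmental / family_size, 1)
                    else 0
  )
}

#' Flatten a block list into a table
#'
#' @param blocks from [detectBlocks()]
#' @return data.frame \code{block chrom_a chrom_b orientation gene_a gene_b
#'   rank_a rank_b bitscore}
#' @export
blocksTable <- function(blocks) {
  if (!length(blocks))
    return(data.frame(block = integer(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      gene_a = character(), gene_b = character(),
                      rank_a = integer(), rank_b = integer(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    cbind(data.frame(block = i, chrom_a = b$chrom_a, chrom_b = b$chrom_b,
                     orientation = b$orientation, stringsAsFactors = FALSE),
          b$anchors)
  }))
}
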