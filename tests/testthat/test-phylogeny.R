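test_that("p-distance counts mismatches over compared sites", {
  aln <- alignmentMatrix(c(a = "ACDE", b = "ACDE", c = "ACDF"))
  D <- pDistance(aln)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 0.25)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("gap handling differs between site policies", {
  aln <- alignmentMatrix(c(a = "AC-E", b = "ACDE"))
  # pairwise deletion: 0 mismatches over the 3 comparable columns
  expect_equal(pDistance(aln, "pairwise_deletion")["a", "b"], 0)
  # complete deletion drops the gapped column for everyone
  aln3 <- alignmentMatrix(c(a = "AC-E", b = "ACDE", c = "GCDE"))
  expect_equal(pDistance(aln3, "complete_deletion")["a", "c"], 1 / 3)
  expect_error(pDistance(alignmentMatrix(c(a = "--AA", b = "AA--")),
                         "pairwise_deletion"), "zero comparable")
  expect_error(alignmentMatrix(c(a = "ACDE")), "at least 2")
})

test_that("Poisson correction is monotone on the p-distance", {
  aln <- alignmentMatrix(c(a = "AAAAAAAAAA", b = "AAAAACCCCC"))
  p <- pDistance(aln)["a", "b"]
  d <- pDistance(aln, model = "poisson")["a", "b"]
  expect_equal(d, -log(1 - p))
  expect_gt(d, p)
})

test_that("three-taxon NJ uses the closed-form star resolution", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- njTree(D)
  expect_equal(ape::Ntip(tr), 3L)
  pl <- ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(pl, D, tolerance = 1e-12)
})

test_that("the additive four-taxon example is reconstructed exactly", {
  nm <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(nm, nm))
  tr <- njTree(D)
  # topology (A,B | C,D) with external branches 1,2,3,4 and internal edge 1
  rt <- ape::root(tr, "D", resolve.root = TRUE)
  mrca <- ape::getMRCA(rt, c("A", "B"))
  expect_setequal(rt$tip.label[phangorn::Descendants(rt, mrca, "tips")[[1L]]],
                  c("A", "B"))
  expect_equal(ape::cophenetic.phylo(tr)[nm, nm], D, tolerance = 1e-12)
  tip_edge <- function(t, lab) t$edge.length[t$edge[, 2L] == match(lab, t$tip.label)]
  expect_equal(vapply(nm, tip_edge, numeric(1), t = tr),
               c(A = 1, B = 2, C = 3, D = 4))
})

test_that("equidistant input joins the lexicographically smallest pair", {
  nm <- c("delta", "alpha", "charlie", "bravo")
  D <- matrix(2, 4, 4, dimnames = list(nm, nm)); diag(D) <- 0
  tr <- njTree(D)
  rt <- ape::root(tr, "delta", resolve.root = TRUE)
  mrca <- ape::getMRCA(rt, c("alpha", "bravo"))
  expect_setequal(rt$tip.label[phangorn::Descendants(rt, mrca, "tips")[[1L]]],
                  c("alpha", "bravo"))
})

test_that("NJ recovers random additive trees (topology and path lengths)", {
  for (i in 1:40) {
    cs <- random_additive_case(sample(4:12, 1L), seed = 1000 + i)
    tr <- njTree(cs$D)
    expect_equal(ape::dist.topo(ape::unroot(cs$tree), tr), 0,
                 ignore_attr = TRUE)
    nm <- rownames(cs$D)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[nm, nm] - cs$D)), 1e-9)
  }
})

test_that("NJ agrees with the independent ape implementation on additive input", {
  for (i in 1:10) {
    cs <- random_additive_case(sample(5:10, 1L), seed = 2000 + i)
    ours <- njTree(cs$D)
    theirs <- ape::nj(cs$D)
    expect_equal(ape::dist.topo(ours, theirs), 0, ignore_attr = TRUE)
  }
})

test_that("non-symmetric or negative matrices are rejected", {
  D <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(njTree(D), "symmetric")
  D2 <- matrix(c(0, -1, 0, -1, 0, 1, 0, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(njTree(D2), "negative")
})

boot_aln <- function() {
  # two well-separated pairs of identical sequences
  alignmentMatrix(c(
    p1 = strrep("A", 30L), p2 = strrep("A", 30L),
    q1 = strrep("W", 30L), q2 = strrep("W", 30L),
    out = paste0(strrep("A", 15L), strrep("C", 15L))))
}

test_that("bootstrap gives 100% support to an unambiguous bipartition", {
  bt <- bootstrapPhylo(boot_aln(), n_reps = 50L, seed = 3)
  # every replicate separates the identical pairs
  expect_true(all(bt$support[-1L] == 100))
})

test_that("bootstrap is deterministic given the seed and needs one", {
  aln <- boot_aln()
  b1 <- bootstrapPhylo(aln, 25L, seed = 9)
  b2 <- bootstrapPhylo(aln, 25L, seed = 9)
  expect_identical(b1$support, b2$support)
  expect_error(bootstrapPhylo(aln, 25L), "seed")
})

# canonical string key per internal node's tip set
famevo_bipartition_keys <- function(tree) {
  n <- ape::Ntip(tree)
  vapply(seq_len(tree$Nnode) + n, function(node) {
    tips <- sort(tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1L]]])
    paste(tips, collapse = "|")
  }, character(1))
}

test_that("supports are invariant under taxon reordering", {
  set.seed(42)
  g <- simGenome(simConfig(family_size = 12L, tandem_cluster_sizes = c(2L, 2L),
                           segmental_blocks = 1L), seed = 5)
  aln <- alignmentMatrix(g$alignment)
  b1 <- bootstrapPhylo(aln, 30L, seed = 11)
  perm <- sample(nrow(aln))
  b2 <- bootstrapPhylo(aln[perm, , drop = FALSE], 30L, seed = 11)
  # compare supports attached to matching bipartitions via the trees
  s1 <- stats::setNames(b1$support, famevo_bipartition_keys(b1$tree))
  s2 <- stats::setNames(b2$support, famevo_bipartition_keys(b2$tree))
  common <- intersect(names(s1), names(s2))
  expect_gt(length(common), 1L)
  expect_identical(s1[common], s2[common])
})

test_that("class assignment follows the smallest reference-containing clade", {
  # ((q1, refI), (q2, (refII_a, refII_b)), (q3, refI2, refII_c))-ish tree
  tr <- ape::read.tree(text = paste0(
    "((q1:0.1,RI:0.1):0.5,(q2:0.1,(RIIa:0.1,RIIb:0.1):0.2):0.5,",
    "((q3:0.1,RI2:0.1):0.1,RIIc:0.2):0.5);"))
  refs <- c(RI = "I", RI2 = "I", RIIa = "II", RIIb = "II", RIIc = "II")
  cl <- assignClasses(tr, refs)
  expect_equal(unname(cl["q1"]), "I")
  expect_equal(unname(cl["q2"]), "II")
  expect_equal(unname(cl["q3"]), "I")
  expect_true(all(cl %in% c(unique(refs), "unresolved")))
})

test_that("mixed-reference clades yield unresolved; no references errors", {
  tr <- ape::read.tree(text = "((q1:0.1,(RA:0.1,RB:0.1):0.1):0.3,(x:0.2,y:0.2):0.3);")
  cl <- assignClasses(tr, c(RA = "I", RB = "II"))
  expect_equal(unname(cl["q1"]), "unresolved")
  expect_error(assignClasses(tr, c(nothere = "I")), "no reference")
})

test_that("synthetic family classes are recovered through the full path", {
  g <- simGenome(simConfig(), seed = 3)
  aln <- alignmentMatrix(g$alignment)
  tr <- njTree(pDistance(aln))
  cl <- assignClasses(tr, g$ref_classes)
  truth <- stats::setNames(g$genes$class[g$genes$family],
                           paste0(g$genes$gene_id[g$genes$family], ".1"))
  expect_gte(mean(cl[names(truth)] == truth), 0.95)
})
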