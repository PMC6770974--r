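# small hand-built panels ------------------------------------------------------

toy_panel <- function(ac, an, pops, chrom = NULL, pos = NULL) {
  ns <- nrow(ac)
  acc <- names(pops)
  colnames(ac) <- colnames(an) <- acc
  makeVariantPanel(chrom %||% rep("c1", ns), pos %||% (seq_len(ns) * 10L),
                   rep("A", ns), rep("G", ns), ac, an, pops)
}

two_pop <- function(nw = 2L, nc = 2L) {
  p <- factor(rep(c("wild", "cultivated"), c(nw, nc)),
              levels = c("wild", "cultivated"))
  names(p) <- c(sprintf("W%d", seq_len(nw)), sprintf("C%d", seq_len(nc)))
  p
}

test_that("variant filters follow the missingness and MAF rules", {
  pops <- two_pop(5L, 5L)
  # site 1: MAF 0.05 exactly (1/20) -> kept; site 2: MAF 0 -> dropped;
  # site 3: 20% missing -> dropped; site 4: common, complete -> kept
  ac <- rbind(c(1, rep(0, 9)), rep(0, 10), c(rep(1, 8), 0, 0),
              rep(1, 10))
  an <- rbind(rep(2, 10), rep(2, 10), c(rep(2, 8), 0, 0), rep(2, 10))
  mode(ac) <- "integer"; mode(an) <- "integer"
  f <- filterVariants(toy_panel(ac, an, pops))
  expect_equal(positionsOf(f)$pos, c(10L, 40L))
  # MAF just under the cutoff is removed
  ac2 <- rbind(c(rep(1, 1), rep(0, 9)))  # 1/20 = 0.05
  f2 <- filterVariants(toy_panel(ac2 * 0L, matrix(2L, 1, 10), pops),
                       min_maf = 0.05)
  expect_equal(length(positionsOf(f2)$pos), 0L)
})

test_that("sliding windows tile and truncate as specified", {
  w <- makeWindows(30000)
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(20000, 30000, 30000))
  w2 <- makeWindows(15000)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$end, c(15000, 15000))
  w3 <- makeWindows(50000, size = 10000, step = 10000)
  expect_true(all(w3$end - w3$start == 10000))
  expect_error(makeWindows(50000, size = 5000, step = 10000), "gaps")
})

test_that("window pi matches the worked single-site example", {
  pops <- two_pop(2L, 2L)
  ac <- matrix(c(1L, 1L, 0L, 0L), 1, 4)   # 2/2 split among wild alleles
  an <- matrix(c(2L, 2L, 0L, 0L), 1, 4)
  panel <- toy_panel(ac, an, pops, pos = 50L)
  pi <- windowPi(panel, "wild", list(c1 = data.frame(start = 0L, end = 100L)))
  expect_equal(pi$pi, (4 / 3) * 0.5 / 100, tolerance = 1e-12)
  expect_equal(pi$pi, 0.006667, tolerance = 1e-4)
  expect_equal(pi$n_snps, 1L)
  # a window with no SNPs has pi 0
  pi2 <- windowPi(panel, "cultivated",
                  list(c1 = data.frame(start = 0L, end = 100L)))
  expect_equal(pi2$pi, 0)
})

test_that("window pi equals the explicit pairwise-difference oracle", {
  for (i in 1:50) {
    set.seed(7000 + i)
    na <- sample(2:6, 1L)
    ns <- sample(1:10, 1L)
    span <- 200L
    an <- matrix(sample(0:2, ns * na, replace = TRUE,
                        prob = c(0.1, 0.1, 0.8)), ns, na)
    ac <- matrix(0L, ns, na)
    ac[] <- vapply(seq_len(ns * na),
                   function(k) sample.int(an[k] + 1L, 1L) - 1L, integer(1))
    pops <- factor(rep("wild", na)); names(pops) <- sprintf("A%d", 1:na)
    panel <- toy_panel(ac, an, pops, pos = sort(sample(span, ns)))
    pi <- windowPi(panel, "wild",
                   list(c1 = data.frame(start = 0L, end = span)))
    expect_equal(pi$pi, oracle_window_pi(ac, an, span), tolerance = 1e-12)
  }
})

test_that("each interior SNP contributes to exactly size/step windows", {
  set.seed(88)
  pops <- two_pop(3L, 0L)
  ns <- 120L
  pos <- sort(sample(2e5, ns))
  ac <- matrix(1L, ns, 3L); an <- matrix(2L, ns, 3L)
  panel <- toy_panel(ac, an, pops, pos = pos)
  w <- makeWindows(2e5)
  pi <- windowPi(panel, "wild", list(c1 = w))
  interior <- pos - 1L >= 10000  # sites before the second window's start
  expect_equal(sum(pi$n_snps), sum(interior) * 2L + sum(!interior))
})

test_that("pi is invariant under accession relabeling and allele swap", {
  set.seed(15)
  pops <- two_pop(4L, 0L)
  ns <- 30L
  an <- matrix(2L, ns, 4L)
  ac <- matrix(sample(0:2, ns * 4L, replace = TRUE), ns, 4L)
  w <- list(c1 = makeWindows(400L, 100L, 100L))
  panel <- toy_panel(ac, an, pops, pos = seq_len(ns) * 13L)
  base <- windowPi(panel, "wild", w)$pi
  perm <- sample(4L)
  panel2 <- toy_panel(ac[, perm], an, pops, pos = seq_len(ns) * 13L)
  expect_equal(windowPi(panel2, "wild", w)$pi, base, tolerance = 1e-12)
  panel3 <- toy_panel(an - ac, an, pops, pos = seq_len(ns) * 13L)  # ref<->alt
  expect_equal(windowPi(panel3, "wild", w)$pi, base, tolerance = 1e-12)
})

test_that("ratio scan orientation and zero conventions", {
  w <- data.frame(chrom = "c1", start = c(0, 10), end = c(10, 20),
                  n_snps = 1L, stringsAsFactors = FALSE)
  pw <- cbind(w, pi = c(0.01, 0))
  pc <- cbind(w, pi = c(0.01, 0.02))
  r <- ratioScan(pw, pc)
  expect_equal(r$ratio, c(1, NA_real_))
  pc2 <- cbind(w, pi = c(0, 0.02))
  expect_equal(ratioScan(pw, pc2)$ratio[1L], 0)
  expect_error(ratioScan(pw[1L, ], pc), "differ")
})

test_that("chromosome baseline flags genes below the chromosome mean", {
  scan <- data.frame(chrom = "c1", start = seq(0, 90, 10),
                     end = seq(10, 100, 10), n_snps = 1L,
                     pi_wild = 0.01, pi_cult = 0.01,
                     ratio = c(0.1, rep(1, 9)), stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = c("gLow", "gHigh"), chrom = "c1",
                      start = c(2L, 55L), end = c(8L, 58L),
                      stringsAsFactors = FALSE)
  b <- chromosomeBaseline(scan, genes)
  expect_true(b$below_chromosome_mean[b$gene_id == "gLow"])
  expect_false(b$below_chromosome_mean[b$gene_id == "gHigh"])
  scan$ratio <- 1
  b2 <- chromosomeBaseline(scan, genes)
  expect_false(any(b2$below_chromosome_mean))
  expect_error(chromosomeBaseline(scan, data.frame(
    gene_id = "x", chrom = "c9", start = 1L, end = 2L)), "no defined")
})

test_that("sweep calls pick exactly the genes over the lowest-ratio windows", {
  n <- 40L
  scan <- data.frame(chrom = "c1", start = (seq_len(n) - 1L) * 10L,
                     end = seq_len(n) * 10L, n_snps = 1L,
                     pi_wild = 0.01, pi_cult = 0.01,
                     ratio = rep(1, n), stringsAsFactors = FALSE)
  scan$ratio[17L] <- 0
  genes <- data.frame(gene_id = c("hit", "miss"), chrom = "c1",
                      start = c(165L, 350L), end = c(168L, 355L),
                      stringsAsFactors = FALSE)
  sw <- callSweeps(scan, genes)
  expect_true(sw$genes$top5_selected[sw$genes$gene_id == "hit"])
  expect_false(sw$genes$top5_selected[sw$genes$gene_id == "miss"])
  # nothing overlapping the low windows -> empty selection
  sw2 <- callSweeps(scan, genes[genes$gene_id == "miss", , drop = FALSE])
  expect_false(any(sw2$genes$top5_selected))
  expect_warning(callSweeps(scan[1:10, ], genes), "fewer than 20")
})

test_that("planted sweeps are recovered with few false positives", {
  cfg <- simConfig()
  g <- simGenome(cfg, seed = 2)
  p <- simPopulation(cfg, g$genes, seed = 2)
  panel <- filterVariants(p$panel)
  chroms <- sort(unique(g$genes$chromosome))
  windows <- lapply(stats::setNames(chroms, chroms),
                    function(ch) makeWindows(cfg$chrom_length))
  scan <- ratioScan(windowPi(panel, "wild", windows),
                    windowPi(panel, "cultivated", windows))
  sw <- callSweeps(scan, p$gene_regions)
  m <- merge(sw$genes, p$truth, by = "gene_id")
  expect_gte(mean(m$top5_selected[m$swept]), 0.9)
  expect_lte(mean(m$top5_selected[!m$swept]), 0.05)
})

test_that("the filter-scan path is deterministic", {
  cfg <- simConfig(n_chromosomes = 1L, genes_per_chromosome = 60L,
                   family_size = 8L, tandem_cluster_sizes = 2L,
                   segmental_blocks = 1L, n_wild = 10L, n_cult = 20L)
  g <- simGenome(cfg, seed = 4)
  run <- function() {
    p <- simPopulation(cfg, g$genes, seed = 4)
    panel <- filterVariants(p$panel)
    w <- list(chr01 = makeWindows(cfg$chrom_length))
    ratioScan(windowPi(panel, "wild", w), windowPi(panel, "cultivated", w))
  }
  expect_identical(run(), run())
})

test_that("accession tree separates duplicated and divergent accessions", {
  pops <- two_pop(3L, 3L)
  # wild fixed 0/0, cultivated fixed 1/1, accessions W1 and W2 identical
  ns <- 25L
  ac <- cbind(matrix(0L, ns, 3L), matrix(2L, ns, 3L))
  an <- matrix(2L, ns, 6L)
  panel <- toy_panel(ac, an, pops, pos = seq_len(ns) * 7L)
  tr <- accessionTree(panel, data.frame(chrom = "c1", start = 1L,
                                        end = 1000L))
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D["W1", "W2"], 0, tolerance = 1e-12)
  expect_gt(min(D[c("W1", "W2", "W3"), c("C1", "C2", "C3")]), 0.5)
  # the two populations form clean sides of one bipartition
  rt <- ape::root(tr, "C1", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rt, c("W1", "W2", "W3")))
})

test_that("VCF round-trip preserves genotypes, including half-missing", {
  pops <- two_pop(2L, 2L)
  ac <- matrix(c(0L, 1L, 2L, 1L,
                 1L, 0L, 0L, 0L), 2, 4, byrow = TRUE)
  an <- matrix(c(2L, 2L, 2L, 1L,
                 2L, 0L, 2L, 2L), 2, 4, byrow = TRUE)
  panel <- toy_panel(ac, an, pops, pos = c(100L, 200L))
  vcf <- tempfile(fileext = ".vcf")
  writeVcfPanel(panel, vcf)
  poptsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(accession = names(pops),
                                population = as.character(pops)),
                     poptsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readVcfPanel(vcf, poptsv)
  expect_equal(unname(back@ac), unname(panel@ac))
  expect_equal(unname(back@an), unname(panel@an))
  expect_equal(positionsOf(back)$pos, c(100L, 200L))
})

test_that("multi-allelic sites are dropped with a warning on read", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
               "c1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
               "c1\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2"), vcf)
  poptsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(accession = c("S1", "S2"),
                                population = c("wild", "cultivated")),
                     poptsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(p <- readVcfPanel(vcf, poptsv), "multi-allelic")
  expect_equal(length(positionsOf(p)$pos), 1L)
})
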