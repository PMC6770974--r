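test_that("GFF3 loading builds gene models with exons in genomic order", {
  gff <- write_toy_gff(list(
    g1 = list(chrom = "chr1", start = 1000L, strand = "+",
              exon_lens = c(300L, 300L)),
    g2 = list(chrom = "chr1", start = 5000L, strand = "-",
              exon_lens = c(150L, 150L, 150L))
  ))
  cds <- write_toy_fasta(c(g1.1 = toy_orf(200L), g2.1 = toy_orf(150L)))
  pep <- write_toy_fasta(c(g1.1 = strrep("M", 199L), g2.1 = strrep("M", 149L)))
  cat <- loadAnnotation(gff, pep, cds)
  tx <- transcriptTable(cat)
  expect_equal(nrow(tx), 2L)
  expect_equal(tx$n_exons[tx$gene_id == "g1"], 2L)
  ex <- exonsOf(cat, "g2.1")
  expect_equal(nrow(ex), 3L)
  # minus-strand exons still reported in genomic (ascending) order
  expect_true(all(diff(ex[, 1L]) > 0))
  expect_equal(tx$strand[tx$gene_id == "g2"], "-")
})

test_that("malformed GFF3 lines are reported by line number", {
  bad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\ttest\tgene\t1\t100"), bad)
  expect_error(loadAnnotation(bad), "line 3")
})

test_that("out-of-frame CDS is flagged and left unset, gene retained", {
  gff <- write_toy_gff(list(
    g1 = list(chrom = "chr1", start = 100L, strand = "+", exon_lens = 50L)))
  cds <- write_toy_fasta(c(g1.1 = "ATGGGGTTTA"))  # length 10
  expect_warning(cat <- loadAnnotation(gff, cds_path = cds),
                 "not divisible by 3")
  tx <- transcriptTable(cat)
  expect_false(tx$cds_ok)
  expect_equal(nrow(tx), 1L)
  expect_length(cdsSeqs(cat), 0L)
})

make_family_catalog <- function() {
  gff <- write_toy_gff(list(
    gA = list(chrom = "chr1", start = 1000L, strand = "+",
              exon_lens = c(700L, 700L)),
    gB = list(chrom = "chr1", start = 9000L, strand = "+",
              exon_lens = c(700L, 700L)),
    gC = list(chrom = "chr2", start = 1000L, strand = "-",
              exon_lens = c(700L, 700L))
  ))
  # gA has two qualifying transcripts (420 aa and 390 aa peptides)
  gff_lines <- readLines(gff)
  extra <- c(
    "chr1\ttest\tmRNA\t1000\t2400\t.\t+\t.\tID=gA.2;Parent=gA",
    "chr1\ttest\texon\t1000\t1699\t.\t+\t.\tID=gA.2.e1;Parent=gA.2",
    "chr1\ttest\texon\t1800\t2400\t.\t+\t.\tID=gA.2.e2;Parent=gA.2")
  writeLines(c(gff_lines, extra), gff)
  cds <- write_toy_fasta(c(gA.1 = toy_orf(422L), gA.2 = toy_orf(392L),
                           gB.1 = toy_orf(422L), gC.1 = toy_orf(422L)))
  pepseq <- function(n) paste0("M", strrep("A", n - 1L))
  pep <- write_toy_fasta(c(gA.1 = pepseq(420L), gA.2 = pepseq(390L),
                           gB.1 = pepseq(420L), gC.1 = pepseq(420L)))
  loadAnnotation(gff, pep, cds)
}

test_that("three-domain rule defines family membership", {
  cat <- make_family_catalog()
  hits <- rbind(full_domain_hits(c("gA.1", "gA.2", "gB.1")),
                full_domain_hits("gC.1")[1:2, ])  # gC: only two domains
  fc <- selectFamily(cat, hits)
  m <- familyMembers(fc)
  expect_setequal(m$gene_id, c("gA", "gB"))
  expect_false("gC" %in% m$gene_id)
  # longest peptide kept for the two-transcript locus
  expect_equal(m$transcript_id[m$gene_id == "gA"], "gA.1")
  expect_equal(m$length_aa[m$gene_id == "gA"], 420L)
})

test_that("membership survives hit-table permutation and is idempotent", {
  cat <- make_family_catalog()
  hits <- full_domain_hits(c("gA.1", "gA.2", "gB.1", "gC.1"))
  fc1 <- selectFamily(cat, hits)
  set.seed(7)
  fc2 <- selectFamily(cat, hits[sample.int(nrow(hits)), ])
  expect_identical(familyMembers(fc1), familyMembers(fc2))
  # restricting hits to the selected representatives changes nothing
  reps <- familyMembers(fc1)$transcript_id
  fc3 <- selectFamily(cat, hits[hits$gene_id %in% reps, ])
  expect_identical(familyMembers(fc3)$gene_id, familyMembers(fc1)$gene_id)
})

test_that("hits on unknown transcripts and high E-values are rejected", {
  cat <- make_family_catalog()
  expect_error(selectFamily(cat, full_domain_hits("nope.1")), "nope.1")
  weak <- full_domain_hits("gB.1", e_value = 1e-3)  # above 1e-5 cutoff
  fc <- selectFamily(cat, weak)
  expect_equal(nrow(familyMembers(fc)), 0L)
})

test_that("incomplete ORFs are excluded from the family", {
  gff <- write_toy_gff(list(
    g1 = list(chrom = "chr1", start = 100L, strand = "+", exon_lens = 600L)))
  # no ATG start
  cds <- write_toy_fasta(c(g1.1 = paste0("GTG", strrep("GGA", 100L), "TAA")))
  pep <- write_toy_fasta(c(g1.1 = strrep("A", 101L)))
  cat <- loadAnnotation(gff, pep, cds)
  fc <- selectFamily(cat, full_domain_hits("g1.1"))
  expect_equal(nrow(familyMembers(fc)), 0L)
})

test_that("chromosome distribution of the packaged family table peaks at 12", {
  tab <- utils::read.delim(extdata("family_chromosomes_synthetic.tsv"),
                           stringsAsFactors = FALSE)
  d <- chromosomeDistribution(tab)
  expect_equal(d$max_count, 12L)
  expect_equal(unname(d$chromosomes["chr18"]), 12L)
  expect_equal(sum(d$chromosomes), 90L)
  expect_equal(sum(d$scaffolds), 3L)
  # exactly four single-gene chromosomes, as reported for the real family
  expect_equal(sum(d$chromosomes == 1L), 4L)
})

test_that("chromosome distribution handles empty and trivial catalogs", {
  empty <- data.frame(gene_id = character(), chromosome = character())
  expect_equal(chromosomeDistribution(empty)$max_count, 0L)
  three <- data.frame(gene_id = c("a", "b", "c"),
                      chromosome = rep("chr5", 3L))
  expect_equal(unname(chromosomeDistribution(three)$chromosomes["chr5"]), 3L)
})

test_that("protein properties: length, molecular weight, pI ranges", {
  expect_equal(proteinProperties("ACDE")$length_aa, 4L)
  expect_equal(proteinProperties("G")$mw_da, 75.0672, tolerance = 1e-6)
  expect_lt(proteinProperties(strrep("D", 12L))$pi, 7)
  expect_gt(proteinProperties(strrep("K", 12L))$pi, 7)
  expect_error(proteinProperties(""), "non-empty")
  expect_error(proteinProperties("ACB1"), "non-standard")
  # X counts for length but not mass
  px <- proteinProperties("GX")
  expect_equal(px$length_aa, 2L)
  expect_equal(px$mw_da, proteinProperties("G")$mw_da)
})

test_that("molecular weight is additive up to one water mass", {
  set.seed(11)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:10) {
    s1 <- paste(sample(aas, 15L, replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, 9L, replace = TRUE), collapse = "")
    expect_equal(proteinProperties(paste0(s1, s2))$mw_da,
                 proteinProperties(s1)$mw_da + proteinProperties(s2)$mw_da -
                   18.0153,
                 tolerance = 1e-9)
  }
})

test_that("pI bisection converges to |net charge| < 1e-4", {
  set.seed(4)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  for (i in 1:20) {
    pep <- paste(sample(aas, sample(5:80, 1L), replace = TRUE), collapse = "")
    pi <- proteinProperties(pep)$pi
    q <- famevo:::.netCharge(famevo:::.aaCounts(pep)$counts, pi)
    expect_lt(abs(q), 1e-4)
  }
})

test_that("exon profiles match the printed six/eight-exon paralog set", {
  # exon counts as reported for GmLac13 and its four tree neighbours
  spec <- list(GmLac13 = 6L, GmLac68 = 8L, GmLac67 = 8L, GmLac40 = 8L,
               GmLac5 = 8L)
  genes <- lapply(spec, function(n)
    list(chrom = "chr1", start = 1000L, strand = "+",
         exon_lens = rep(200L, n)))
  gff <- write_toy_gff(genes)
  cat <- loadAnnotation(gff)
  for (g in names(spec)) {
    p <- exonProfile(cat, paste0(g, ".1"))
    expect_equal(p$exon_count, spec[[g]])
    expect_equal(p$intron_count, spec[[g]] - 1L)
  }
})

test_that("single-exon genes have zero introns", {
  gff <- write_toy_gff(list(
    g1 = list(chrom = "chr1", start = 10L, strand = "+", exon_lens = 900L)))
  cat <- loadAnnotation(gff)
  p <- exonProfile(cat, "g1.1")
  expect_equal(p$exon_count, 1L)
  expect_equal(p$intron_count, 0L)
})
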