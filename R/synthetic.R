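# Deterministic synthetic-data generators with ground truth. They emulate
# the inputs of a genome-wide gene-family study: a gene catalog with planted
# tandem arrays and duplicated segments, family CDS evolved along a class
# tree at chosen Ks and omega, tissue/infection FPKM tables with planted
# expression classes, and a two-population SNP panel with planted
# low-diversity sweep regions. Every generator is a pure function of
# (config, seed).

#' Default simulation configuration
#'
#' Returns the full parameter list; any element can be overridden through
#' \code{...}. Defaults mirror the study conditions the pipeline targets:
#' a multi-chromosome genome with tandem arrays and >= 5-anchor duplicated
#' segments, a five-class family, a wild/cultivated panel of 62 + 240
#' accessions with three planted sweep regions at a ten-fold diversity
#' reduction, and nine-tissue / five-timepoint expression tables.
#'
#' @param ... named overrides of the defaults
#' @return named list of parameters
#' @export
simConfig <- function(...) {
  cfg <- list(
    # genome layout
    n_chromosomes = 4L, chrom_length = 1e6, genes_per_chromosome = 150L,
    family_size = 40L,
    tandem_cluster_sizes = c(3L, 2L, 2L, 3L),
    segmental_blocks = 3L, block_anchors = 6L,
    family_anchor_offsets = c(1L, 4L),  # within-region offsets of family anchors
    frac_decoy_domains = 0.08,          # non-family genes given 1-2 domains
    frac_multi_transcript = 0.10,       # family loci with a second, shorter mRNA
    # family sequence evolution
    cds_codons = 450L, omega = 0.2,
    ks_class = 0.8, ks_member = 0.15, ks_ref = 0.3,
    pair_extra_ks = c(0, 0.5),          # extra divergence of segmental pairs
    n_classes = 5L, refs_per_class = 2L,
    # expression
    tissues = c("root", "root_hair", "nodules", "pod", "seed", "stem",
                "sam", "leaves", "flower"),
    timepoints = c("0h", "0.5h", "3h", "6h", "12h"),
    frac_high = 0.12, frac_specific = 0.09, frac_inactive = 0.12,
    frac_induced = 0.10, frac_suppressed = 0.13,
    noise_sdlog = 0.1,
    # population panel
    n_wild = 62L, n_cult = 240L, theta_wild = 0.003,
    bottleneck_n = 30L, bottleneck_gen = 20L,
    missing_rate = 0.02, frac_high_missing = 0.02,
    sweep_regions = 3L, sweep_span = 80000, sweep_reduction = 10
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  stopifnot(cfg$sweep_reduction > 1, cfg$family_size > 0)
  cfg
}

.SENSE_CODONS <- NULL  # initialized on first use

.senseCodons <- function() {
  .codonTables()
  names(.kaksCache$aa)[!.kaksCache$is_stop]
}

.randomCds <- function(n_codons) {
  sense <- .senseCodons()
  body <- sample(setdiff(sense, "ATG"), n_codons, replace = TRUE)
  c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
}

# substitution-accumulation on a codon vector: synonymous proposals are
# always accepted, nonsynonymous ones with probability omega, stops never;
# runs until n_syn_events synonymous substitutions have been applied. The
# first (ATG) and last (stop) codons are kept intact so the reading frame
# stays a complete ORF.
.evolveCodons <- function(codons, n_syn_events, omega) {
  .codonTables()
  aa <- .kaksCache$aa
  is_stop <- .kaksCache$is_stop
  nts <- c("A", "C", "G", "T")
  syn_done <- 0L; nonsyn_done <- 0L
  L <- length(codons)
  while (syn_done < n_syn_events) {
    ci <- sample.int(L - 2L, 1L) + 1L
    p <- sample.int(3L, 1L)
    cur <- codons[ci]
    nt <- sample(setdiff(nts, substr(cur, p, p)), 1L)
    nxt <- cur
    substr(nxt, p, p) <- nt
    if (is_stop[nxt]) next
    if (aa[nxt] == aa[cur]) {
      codons[ci] <- nxt
      syn_done <- syn_done + 1L
    } else if (stats::runif(1L) < omega) {
      codons[ci] <- nxt
      nonsyn_done <- nonsyn_done + 1L
    }
  }
  attr(codons, "syn_events") <- syn_done
  attr(codons, "nonsyn_events") <- nonsyn_done
  codons
}

.synSiteTotal <- function(codons) {
  .codonTables()
  sum(.kaksCache$syn_sites[codons])
}

#' Evolve a CDS pair to a target synonymous divergence
#'
#' An ancestor is sampled uniformly over sense codons; substitutions are
#' applied independently along two descendant lineages (half the events
#' each) by per-site proposals where synonymous changes are accepted with
#' probability 1 and nonsynonymous changes with probability \code{omega};
#' stop codons are never introduced. The process runs until the expected
#' synonymous divergence (accepted synonymous events per synonymous site,
#' multiple hits included) reaches \code{ks_target}.
#'
#' @param length_codons number of codons (>= 50)
#' @param ks_target target synonymous divergence (> 0, or 0 for an identical
#'   pair); targets near or beyond Jukes-Cantor saturation trigger a warning
#' @param omega nonsynonymous/synonymous acceptance ratio
#' @param seed integer seed
#' @return list with \code{cds_a}, \code{cds_b} (strings), and realized
#'   event counts \code{syn_events}, \code{nonsyn_events}
#' @export
simCdsPair <- function(length_codons, ks_target, omega, seed) {
  if (length_codons < 50L) stop("need at least 50 codons")
  if (ks_target < 0) stop("ks_target must be nonnegative")
  if (ks_target > 2)
    warning("ks_target beyond Jukes-Cantor saturation range; estimates will be unstable")
  set.seed(seed)
  anc <- .randomCds(length_codons - 2L)  # ATG + body + stop = length_codons
  s_total <- .synSiteTotal(anc)
  total_events <- round(ks_target * s_total)
  ea <- total_events %/% 2L
  eb <- total_events - ea
  a <- .evolveCodons(anc, ea, omega)
  b <- .evolveCodons(anc, eb, omega)
  list(cds_a = paste(a, collapse = ""), cds_b = paste(b, collapse = ""),
       syn_events = attr(a, "syn_events") + attr(b, "syn_events"),
       nonsyn_events = attr(a, "nonsyn_events") + attr(b, "nonsyn_events"))
}

.translateCodons <- function(codons) {
  aa <- .kaksCache$aa[codons]
  paste(aa[aa != "*"], collapse = "")
}

#' Generate a synthetic genome bundle with planted duplications
#'
#' Places genes on chromosomes, plants tandem arrays (adjacent family genes),
#' duplicated segments (>= \code{block_anchors} collinear anchor pairs, a
#' subset of which are family pairs), evolves family CDS along a class tree,
#' and emits the domain-hit and all-vs-all homolog tables consistent with
#' that structure. Family loci may carry a second, shorter transcript to
#' exercise representative-transcript selection.
#'
#' @param config from [simConfig()]
#' @param seed integer seed
#' @return list with \code{genes} (full gene table incl. truth columns
#'   \code{family}, \code{class}, \code{tandem}, \code{segmental}),
#'   \code{transcripts}, \code{sequences} (per-transcript CDS/peptide),
#'   \code{domain_hits}, \code{homolog_hits}, \code{gene_order},
#'   \code{alignment} (named peptide vector: family representatives +
#'   references), \code{ref_classes} (named vector), \code{pairs} (planted
#'   collinear family pairs with their extra-Ks truth)
#' @export
simGenome <- function(config = simConfig(), seed = 1L) {
  set.seed(seed)
  nc <- config$n_chromosomes
  gpc <- config$genes_per_chromosome
  n_genes <- nc * gpc
  chroms <- sprintf("chr%02d", seq_len(nc))

  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chromosome = rep(chroms, each = gpc),
    rank = rep(seq_len(gpc), nc),
    stringsAsFactors = FALSE
  )
  spacing <- config$chrom_length / (gpc + 1)
  glen <- round(stats::runif(n_genes, 2000, 4000))
  genes$start <- as.integer(round((genes$rank - 0.5) * spacing +
                                  stats::runif(n_genes, -spacing / 8, spacing / 8)))
  genes$end <- genes$start + glen
  genes$strand <- sample(c("+", "-"), n_genes, replace = TRUE)

  ## ---- plant family structure on gene ranks -------------------------------
  reserved <- new.env(parent = emptyenv())  # chromosome -> reserved ranks
  for (ch in chroms) assign(ch, integer(0), envir = reserved)
  take <- function(ch, ranks) assign(ch, c(get(ch, envir = reserved), ranks),
                                     envir = reserved)
  free_run <- function(ch, len, sep = 3L) {
    used <- get(ch, envir = reserved)
    for (try in seq_len(200L)) {
      s <- sample.int(gpc - len - sep, 1L) + 1L
      if (!any((s - sep):(s + len + sep - 1L) %in% used)) return(s)
    }
    stop("config infeasible: cannot place structures on ", ch)
  }

  fam <- character(0)
  tandem <- character(0)
  units <- list()  # class-assignment units

  for (sz in config$tandem_cluster_sizes) {
    ch <- sample(chroms, 1L)
    s <- free_run(ch, sz)
    take(ch, (s - 2L):(s + sz + 1L))
    ids <- genes$gene_id[genes$chromosome == ch & genes$rank %in% s:(s + sz - 1L)]
    fam <- c(fam, ids); tandem <- c(tandem, ids)
    units[[length(units) + 1L]] <- ids
  }

  seg_pairs <- data.frame(gene_a = character(), gene_b = character(),
                          extra_ks = numeric(), stringsAsFactors = FALSE)
  segmental <- character(0)
  anchors_all <- list()
  for (b in seq_len(config$segmental_blocks)) {
    chs <- sample(chroms, 2L, replace = length(chroms) < 2L)
    na <- config$block_anchors
    sa <- free_run(chs[1L], na)
    sb <- free_run(chs[2L], na)
    take(chs[1L], (sa - 2L):(sa + na + 1L))
    take(chs[2L], (sb - 2L):(sb + na + 1L))
    ida <- genes$gene_id[genes$chromosome == chs[1L] &
                         genes$rank %in% sa:(sa + na - 1L)]
    idb <- genes$gene_id[genes$chromosome == chs[2L] &
                         genes$rank %in% sb:(sb + na - 1L)]
    anchors_all[[b]] <- data.frame(gene_a = ida, gene_b = idb,
                                   stringsAsFactors = FALSE)
    off <- config$family_anchor_offsets
    off <- off[off <= na]
    ek <- sample(config$pair_extra_ks, length(off), replace = TRUE)
    for (k in seq_along(off)) {
      pa <- ida[off[k]]; pb <- idb[off[k]]
      fam <- c(fam, pa, pb); segmental <- c(segmental, pa, pb)
      seg_pairs <- rbind(seg_pairs,
                         data.frame(gene_a = pa, gene_b = pb,
                                    extra_ks = ek[k], stringsAsFactors = FALSE))
      units[[length(units) + 1L]] <- c(pa, pb)
    }
  }

  n_single <- config$family_size - length(fam)
  if (n_single < 0) stop("config infeasible: planted structures exceed family_size")
  while (n_single > 0L) {
    ch <- sample(chroms, 1L)
    s <- free_run(ch, 1L)
    take(ch, (s - 2L):(s + 2L))
    id <- genes$gene_id[genes$chromosome == ch & genes$rank == s]
    fam <- c(fam, id)
    units[[length(units) + 1L]] <- id
    n_single <- n_single - 1L
  }

  genes$family <- genes$gene_id %in% fam
  genes$tandem <- genes$gene_id %in% tandem
  genes$segmental <- genes$gene_id %in% segmental

  ## ---- class tree and family sequences ------------------------------------
  classes <- as.character(as.roman(seq_len(config$n_classes)))
  unit_class <- classes[(seq_along(units) - 1L) %% config$n_classes + 1L]
  gene_class <- stats::setNames(rep(NA_character_, n_genes), genes$gene_id)
  for (i in seq_along(units)) gene_class[units[[i]]] <- unit_class[i]
  genes$class <- unname(gene_class[genes$gene_id])

  root <- .randomCds(config$cds_codons - 2L)
  s_root <- .synSiteTotal(root)
  ev <- function(k) round(k * s_root)
  class_anc <- lapply(classes, function(cl)
    .evolveCodons(root, ev(config$ks_class / 2), config$omega))
  names(class_anc) <- classes

  seqs <- list()  # gene_id -> codon vector
  for (i in seq_along(units)) {
    ids <- units[[i]]
    anc <- class_anc[[unit_class[i]]]
    if (length(ids) == 2L && ids[1L] %in% seg_pairs$gene_a) {
      # segmental pair: shared pair ancestor, then extra divergence
      ek <- seg_pairs$extra_ks[seg_pairs$gene_a == ids[1L]]
      panc <- .evolveCodons(anc, ev(config$ks_member / 2), config$omega)
      half <- ev((config$ks_member + ek) / 2)
      seqs[[ids[1L]]] <- .evolveCodons(panc, half, config$omega)
      seqs[[ids[2L]]] <- .evolveCodons(panc, half, config$omega)
    } else {
      for (id in ids)
        seqs[[id]] <- .evolveCodons(anc, ev(config$ks_member / 2),
                                    config$omega)
    }
  }

  refs <- list()
  for (cl in classes) for (r in seq_len(config$refs_per_class)) {
    refs[[sprintf("REF_%s_%d", cl, r)]] <-
      .evolveCodons(class_anc[[cl]], ev(config$ks_ref / 2), config$omega)
  }
  ref_classes <- stats::setNames(
    rep(classes, each = config$refs_per_class), names(refs))

  ## ---- transcripts and per-transcript sequences ---------------------------
  sense <- .senseCodons()
  tx <- data.frame(
    transcript_id = paste0(genes$gene_id, ".1"),
    gene_id = genes$gene_id, stringsAsFactors = FALSE
  )
  cds_list <- vector("list", n_genes)
  names(cds_list) <- tx$transcript_id
  for (i in seq_len(n_genes)) {
    gid <- genes$gene_id[i]
    cds_list[[i]] <- if (!is.null(seqs[[gid]])) seqs[[gid]]
                     else .randomCds(config$cds_codons - 2L)
  }
  # second, shorter transcript on a fraction of family loci
  multi <- sample(fam, max(0L, round(length(fam) * config$frac_multi_transcript)))
  for (gid in multi) {
    full <- cds_list[[paste0(gid, ".1")]]
    short <- c(full[seq_len(length(full) - 31L)], "TAA")
    tid <- paste0(gid, ".2")
    tx <- rbind(tx, data.frame(transcript_id = tid, gene_id = gid,
                               stringsAsFactors = FALSE))
    cds_list[[tid]] <- short
  }

  cds_str <- vapply(cds_list, paste, character(1), collapse = "")
  pep_str <- vapply(cds_list, .translateCodons, character(1))

  ## ---- domain hits ---------------------------------------------------------
  fam_tx <- tx$transcript_id[tx$gene_id %in% fam]
  dh <- do.call(rbind, lapply(fam_tx, function(t) {
    len <- nchar(pep_str[[t]])
    data.frame(gene_id = t, domain = c("CuOx", "CuOx2", "CuOx3"),
               e_value = 10^stats::runif(3, -60, -20),
               qstart = c(10L, round(len * 0.4), round(len * 0.75)),
               qend = c(round(len * 0.3), round(len * 0.65), len - 5L),
               stringsAsFactors = FALSE)
  }))
  decoys <- sample(setdiff(genes$gene_id, fam),
                   round(config$frac_decoy_domains * (n_genes - length(fam))))
  dd <- do.call(rbind, lapply(decoys, function(g) {
    t <- paste0(g, ".1")
    nd <- sample(1:2, 1L)
    doms <- sample(c("CuOx", "CuOx2", "CuOx3"), nd)
    len <- nchar(pep_str[[t]])
    data.frame(gene_id = t, domain = doms,
               e_value = 10^stats::runif(nd, -30, -8),
               qstart = 10L, qend = len - 10L, stringsAsFactors = FALSE)
  }))
  domain_hits <- rbind(dh, dd)
  domain_hits <- domain_hits[sample.int(nrow(domain_hits)), , drop = FALSE]
  rownames(domain_hits) <- NULL

  ## ---- homolog hits --------------------------------------------------------
  anchor_hits <- do.call(rbind, lapply(anchors_all, function(a)
    data.frame(query = a$gene_a, subject = a$gene_b,
               evalue = 10^stats::runif(nrow(a), -80, -30),
               bitscore = round(stats::runif(nrow(a), 300, 600)),
               stringsAsFactors = FALSE)))
  nbg <- 200L
  bg <- data.frame(query = sample(genes$gene_id, nbg, replace = TRUE),
                   subject = sample(genes$gene_id, nbg, replace = TRUE),
                   evalue = 10^stats::runif(nbg, -12, -2),
                   bitscore = round(stats::runif(nbg, 40, 80)),
                   stringsAsFactors = FALSE)
  bg <- bg[bg$query != bg$subject, , drop = FALSE]
  homolog_hits <- rbind(anchor_hits, bg)
  rownames(homolog_hits) <- NULL

  ## ---- assemble ------------------------------------------------------------
  fam_rep <- paste0(fam, ".1")
  alignment <- c(stats::setNames(pep_str[fam_rep], fam_rep),
                 vapply(refs, .translateCodons, character(1)))

  list(
    genes = genes,
    transcripts = tx,
    sequences = list(cds = cds_str, peptide = pep_str),
    domain_hits = domain_hits,
    homolog_hits = homolog_hits,
    gene_order = genes[, c("gene_id", "chromosome", "rank")],
    alignment = alignment,
    ref_classes = ref_classes,
    pairs = seg_pairs,
    config = config, seed = seed
  )
}

#' Generate expression tables with planted classes
#'
#' Tissue matrix: planted constitutive-high genes (every tissue several-fold
#' above the grand mean), tissue-specific genes (one dominant tissue, tau >=
#' 0.9 by construction), inactive genes (< 1 FPKM everywhere) and broad
#' background genes. Infection time course: planted induced / suppressed /
#' unchanged genes with |log2 change| >= 2 at one or more post-baseline
#' points. Multiplicative lognormal noise on every entry.
#'
#' @param config from [simConfig()]
#' @param gene_ids genes to simulate (rows of both tables)
#' @param seed integer seed
#' @return list with \code{tissue} (matrix), \code{timecourse} (matrix, first
#'   column the 0 h baseline) and \code{truth} (data.frame \code{gene_id
#'   tissue_label specific_tissue time_label})
#' @export
simExpression <- function(config = simConfig(), gene_ids, seed = 1L) {
  set.seed(seed)
  ng <- length(gene_ids)
  ts <- config$tissues
  nt <- length(ts)
  fr <- c(config$frac_high, config$frac_specific, config$frac_inactive)
  if (sum(fr) > 1) stop("expression class fractions exceed 1")
  n_high <- round(fr[1] * ng); n_spec <- round(fr[2] * ng)
  n_inact <- round(fr[3] * ng)
  lab <- sample(c(rep("high", n_high), rep("specific", n_spec),
                  rep("inactive", n_inact),
                  rep("broad", ng - n_high - n_spec - n_inact)))

  m <- matrix(0, ng, nt, dimnames = list(gene_ids, ts))
  spec_tissue <- rep(NA_character_, ng)
  for (i in seq_len(ng)) {
    m[i, ] <- switch(lab[i],
      broad = stats::rlnorm(nt, log(8), 0.4),
      inactive = stats::runif(nt, 0, 0.5),
      specific = {
        j <- sample.int(nt, 1L)
        spec_tissue[i] <- ts[j]
        peak <- stats::rlnorm(1, log(40), 0.3)
        v <- stats::runif(nt, 0, 0.05) * peak
        v[j] <- peak
        v
      },
      high = stats::runif(nt, 4, 7)  # multipliers of the grand mean
    )
  }
  hi <- lab == "high"
  if (any(hi)) {
    s_other <- sum(m[!hi, , drop = FALSE])
    mult_sum <- sum(m[hi, , drop = FALSE])
    gm <- s_other / (ng * nt - mult_sum)
    m[hi, ] <- m[hi, , drop = FALSE] * gm
  }
  m <- m * stats::rlnorm(length(m), 0, config$noise_sdlog)

  tp <- config$timepoints
  np <- length(tp)
  fr2 <- c(config$frac_induced, config$frac_suppressed)
  if (sum(fr2) > 1) stop("timecourse class fractions exceed 1")
  n_ind <- round(fr2[1] * ng); n_sup <- round(fr2[2] * ng)
  tlab <- sample(c(rep("induced", n_ind), rep("suppressed", n_sup),
                   rep("unchanged", ng - n_ind - n_sup)))
  tc <- matrix(0, ng, np, dimnames = list(gene_ids, tp))
  for (i in seq_len(ng)) {
    tc[i, ] <- switch(tlab[i],
      induced = {
        base <- stats::rlnorm(1, log(3), 0.3)
        v <- base * 2^stats::runif(np, -0.5, 0.5)
        v[1L] <- base
        v[sample(2:np, 1L)] <- base * 2^stats::runif(1, 2.2, 4)
        v
      },
      suppressed = {
        base <- stats::rlnorm(1, log(8), 0.3)
        v <- base * 2^stats::runif(np, -0.5, 0.5)
        v[1L] <- base
        v[sample(2:np, 1L)] <- base * 2^-stats::runif(1, 2.2, 4)
        v
      },
      unchanged = {
        base <- stats::rlnorm(1, log(4), 0.5)
        base * 2^c(0, stats::runif(np - 1L, -0.6, 0.6))
      })
  }
  tc <- tc * stats::rlnorm(length(tc), 0, config$noise_sdlog)

  list(tissue = m, timecourse = tc,
       truth = data.frame(gene_id = gene_ids, tissue_label = lab,
                          specific_tissue = spec_tissue, time_label = tlab,
                          stringsAsFactors = FALSE))
}

# mean heterozygosity of the truncated 1/f ancestral frequency distribution
.sfsMeanHet <- function(f0 = 0.01) {
  f <- seq(f0, 1 - f0, length.out = 4096L)
  w <- 1 / f
  sum(2 * f * (1 - f) * w) / sum(w)
}

#' Generate a two-population SNP panel with planted sweep regions
#'
#' Ancestral (wild) allele frequencies are drawn from a neutral-like 1/f
#' spectrum scaled so the wild per-bp diversity matches \code{theta_wild};
#' cultivated frequencies derive from them by \code{bottleneck_gen}
#' generations of Wright-Fisher binomial drift at size \code{bottleneck_n}
#' (a domestication bottleneck), and inside planted sweep regions an extra
#' \code{sweep_reduction}-fold heterozygosity reduction is applied by fixing
#' sites toward their major allele. Diploid genotypes are then sampled per
#' accession with the configured missingness; a small fraction of sites gets
#' 30\% missing calls to exercise the missingness filter.
#'
#' @param config from [simConfig()]
#' @param genes gene table (data.frame \code{gene_id chromosome start end}
#'   plus logical \code{family}), e.g. from [simGenome()]; sweep regions are
#'   centered on \code{sweep_regions} family genes on distinct chromosomes
#' @param seed integer seed
#' @return list with \code{panel} (a [VariantPanel-class]), \code{regions}
#'   (planted sweep regions, 1-based inclusive), \code{gene_regions} (BED-
#'   style table of all genes) and \code{truth} (data.frame \code{gene_id
#'   swept})
#' @export
simPopulation <- function(config = simConfig(), genes, seed = 1L) {
  set.seed(seed)
  chroms <- sort(unique(genes$chromosome))
  L <- config$chrom_length
  eh <- .sfsMeanHet()
  n_sites_chr <- round(config$theta_wild * L / eh)

  fam_genes <- genes[genes$family, , drop = FALSE]
  reg_chr <- sample(chroms, config$sweep_regions, replace =
                      config$sweep_regions > length(chroms))
  regions <- do.call(rbind, lapply(seq_len(config$sweep_regions), function(i) {
    cand <- fam_genes[fam_genes$chromosome == reg_chr[i], , drop = FALSE]
    if (!nrow(cand)) cand <- fam_genes
    g <- cand[sample.int(nrow(cand), 1L), ]
    mid <- (g$start + g$end) %/% 2L
    s <- max(1L, mid - as.integer(config$sweep_span / 2))
    e <- s + as.integer(config$sweep_span) - 1L
    if (e > L) { warning("sweep region clipped at chromosome end"); e <- as.integer(L) }
    data.frame(chrom = g$chromosome, start = s, end = e,
               anchor_gene = g$gene_id, stringsAsFactors = FALSE)
  }))

  n_acc <- config$n_wild + config$n_cult
  acc <- c(sprintf("W%03d", seq_len(config$n_wild)),
           sprintf("C%03d", seq_len(config$n_cult)))
  pops <- factor(stats::setNames(
    rep(c("wild", "cultivated"), c(config$n_wild, config$n_cult)), acc),
    levels = c("wild", "cultivated"))
  names(pops) <- acc

  all_chrom <- character(0); all_pos <- integer(0)
  ac_list <- list(); an_list <- list()
  f0 <- 0.01
  for (ch in chroms) {
    pos <- sort(sample.int(L, n_sites_chr))
    u <- stats::runif(n_sites_chr)
    fw <- f0 * ((1 - f0) / f0)^u          # wild frequencies, 1/f spectrum
    fc <- fw
    for (g in seq_len(config$bottleneck_gen))
      fc <- stats::rbinom(n_sites_chr, 2L * config$bottleneck_n, fc) /
            (2 * config$bottleneck_n)
    inreg <- rep(FALSE, n_sites_chr)
    for (i in which(regions$chrom == ch))
      inreg <- inreg | (pos >= regions$start[i] & pos <= regions$end[i])
    if (any(inreg)) {
      fix <- inreg & stats::runif(n_sites_chr) > 1 / config$sweep_reduction
      fc[fix] <- round(fc[fix])           # fixed toward the major allele
    }
    f_by_acc <- cbind(matrix(fw, n_sites_chr, config$n_wild),
                      matrix(fc, n_sites_chr, config$n_cult))
    g <- matrix(stats::rbinom(length(f_by_acc), 2L, f_by_acc),
                nrow = n_sites_chr)
    an <- matrix(2L, n_sites_chr, n_acc)
    miss <- matrix(stats::runif(length(g)) < config$missing_rate,
                   nrow = n_sites_chr)
    hi_miss <- stats::runif(n_sites_chr) < config$frac_high_missing
    miss[hi_miss, ] <- matrix(stats::runif(sum(hi_miss) * n_acc) < 0.30,
                              nrow = sum(hi_miss))
    an[miss] <- 0L
    g[miss] <- 0L
    colnames(g) <- colnames(an) <- acc
    all_chrom <- c(all_chrom, rep(ch, n_sites_chr))
    all_pos <- c(all_pos, pos)
    ac_list[[ch]] <- g; an_list[[ch]] <- an
  }
  panel <- makeVariantPanel(
    chrom = all_chrom, pos = all_pos,
    ref = rep("A", length(all_pos)), alt = rep("G", length(all_pos)),
    ac = do.call(rbind, ac_list), an = do.call(rbind, an_list),
    populations = pops)

  gene_regions <- data.frame(gene_id = genes$gene_id,
                             chrom = genes$chromosome,
                             start = genes$start, end = genes$end,
                             stringsAsFactors = FALSE)
  swept <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(regions)))
    swept <- swept | (genes$chromosome == regions$chrom[i] &
                      genes$start <= regions$end[i] &
                      genes$end >= regions$start[i])
  list(panel = panel, regions = regions, gene_regions = gene_regions,
       truth = data.frame(gene_id = genes$gene_id, swept = swept,
                          stringsAsFactors = FALSE))
}

#' Write a variant panel as a minimal VCF
#'
#' Emits biallelic sites with diploid GT fields; genotypes with one called
#' allele are written as half-missing calls.
#'
#' @param panel a [VariantPanel-class]
#' @param path output path
#' @export
writeVcfPanel <- function(panel, path) {
  acc <- accessions(panel)
  gtchar <- function(ac, an) {
    out <- character(length(ac))
    out[an == 0L] <- "./."
    out[an == 2L & ac == 0L] <- "0/0"
    out[an == 2L & ac == 1L] <- "0/1"
    out[an == 2L & ac == 2L] <- "1/1"
    out[an == 1L] <- paste0(ac[an == 1L], "/.")
    out
  }
  gt_cols <- lapply(seq_along(acc),
                    function(j) gtchar(panel@ac[, j], panel@an[, j]))
  gt_str <- do.call(paste, c(gt_cols, sep = "\t"))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", acc), collapse = "\t"),
    paste(panel@chrom, panel@pos, ".", panel@ref, panel@alt, ".", "PASS",
          ".", "GT", gt_str, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write all synthetic inputs of one study to a directory
#'
#' Generates the genome, expression and population components with sub-seeds
#' derived from \code{seed} and writes every file the pipeline consumes:
#' \code{genes.gff3}, \code{pep.fasta}, \code{cds.fasta},
#' \code{domain_hits.tsv}, \code{homolog_hits.tsv}, \code{gene_order.tsv},
#' \code{family_aln.fasta}, \code{ref_classes.tsv}, \code{tissue_fpkm.tsv},
#' \code{infection_fpkm.tsv}, \code{panel.vcf}, \code{populations.tsv},
#' \code{genes.bed}, plus ground-truth tables (\code{truth_*.tsv}).
#'
#' @param dir output directory (created if needed)
#' @param config from [simConfig()]
#' @param seed integer seed
#' @return invisibly, the list of generated objects
#' @export
simulateBundle <- function(dir, config = simConfig(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simGenome(config, seed)
  fam_ids <- sort(g$genes$gene_id[g$genes$family])
  e <- simExpression(config, fam_ids, seed + 1L)
  p <- simPopulation(config, g$genes, seed + 2L)

  fp <- function(f) file.path(dir, f)
  .writeGff3(g, fp("genes.gff3"))
  .writeFasta(g$sequences$peptide, fp("pep.fasta"))
  .writeFasta(g$sequences$cds, fp("cds.fasta"))
  wt <- function(d, f) utils::write.table(d, fp(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(g$domain_hits, "domain_hits.tsv")
  wt(g$homolog_hits, "homolog_hits.tsv")
  wt(g$gene_order, "gene_order.tsv")
  .writeFasta(g$alignment, fp("family_aln.fasta"))
  wt(data.frame(taxon = names(g$ref_classes), class = g$ref_classes),
     "ref_classes.tsv")
  wt(data.frame(gene_id = rownames(e$tissue), e$tissue, check.names = FALSE),
     "tissue_fpkm.tsv")
  wt(data.frame(gene_id = rownames(e$timecourse), e$timecourse,
                check.names = FALSE), "infection_fpkm.tsv")
  writeVcfPanel(p$panel, fp("panel.vcf"))
  wt(data.frame(accession = names(populationsOf(p$panel)),
                population = as.character(populationsOf(p$panel))),
     "populations.tsv")
  bed <- p$gene_regions
  utils::write.table(
    data.frame(bed$chrom, bed$start - 1L, bed$end, bed$gene_id),
    fp("genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wt(g$genes, "truth_genes.tsv")
  wt(e$truth, "truth_expression.tsv")
  wt(p$regions, "truth_regions.tsv")
  wt(p$truth, "truth_sweeps.tsv")
  invisible(list(genome = g, expression = e, population = p))
}

.writeFasta <- function(named_seqs, path) {
  out <- character(2L * length(named_seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(named_seqs))
  out[c(FALSE, TRUE)] <- unname(named_seqs)
  writeLines(out, path)
  invisible(path)
}

.writeGff3 <- function(g, path) {
  genes <- g$genes
  tx <- g$transcripts
  cds_len <- nchar(g$sequences$cds)
  chunks <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    rows <- paste(
      genes$chromosome[i], "famevo_sim", "gene", genes$start[i], genes$end[i],
      ".", genes$strand[i], ".", sprintf("ID=%s", gid), sep = "\t")
    for (tid in tx$transcript_id[tx$gene_id == gid]) {
      clen <- cds_len[[tid]]
      # split the CDS into exons of roughly equal size inside the gene span
      n_ex <- 2L + (i %% 4L)
      span <- genes$end[i] - genes$start[i]
      ex_len <- diff(round(seq(0, clen, length.out = n_ex + 1L)))
      gap <- max(0L, (span - clen) %/% max(1L, n_ex - 1L))
      s <- genes$start[i]
      ex <- matrix(0L, n_ex, 2L)
      for (k in seq_len(n_ex)) {
        ex[k, ] <- c(s, s + ex_len[k] - 1L)
        s <- s + ex_len[k] + gap
      }
      rows <- c(rows, paste(
        genes$chromosome[i], "famevo_sim", "mRNA", ex[1L, 1L], ex[n_ex, 2L],
        ".", genes$strand[i], ".",
        sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"))
      rows <- c(rows, paste(
        genes$chromosome[i], "famevo_sim", "exon", ex[, 1L], ex[, 2L],
        ".", genes$strand[i], ".",
        sprintf("ID=%s.exon%d;Parent=%s", tid, seq_len(n_ex), tid),
        sep = "\t"))
    }
    chunks[[i]] <- rows
  }
  writeLines(c("##gff-version 3", unlist(chunks)), path)
  invisible(path)
}
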