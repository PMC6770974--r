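# End-to-end orchestration: catalog -> phylogeny -> duplication ->
# expression -> selection, with plain-text TSV/Newick interchange between
# stages so each stage is independently re-runnable and testable.

#' Build a run configuration
#'
#' File paths default to the layout written by [simulateBundle()]. Every
#' analysis parameter defaults to the value used throughout the package:
#' domain/homolog E-value 1e-5, >= 5 anchors per collinear block (rank gap
#' <= 25), 3-fold grand-mean rule for high expression, tau >= 0.85 with a
#' 10-FPKM peak for tissue specificity, 1-FPKM inactivity floor, log2
#' response thresholds +1/-1 with pseudocount 0.001, clock rate 6.1e-9,
#' 20 kb / 10 kb diversity windows, missingness <= 10%, MAF >= 5%, lowest-5%
#' sweep quantile, 1000 bootstrap replicates.
#'
#' @param input_dir directory holding the input bundle
#' @param output_dir directory for stage outputs (created if needed)
#' @param seed integer seed (bootstrap resampling)
#' @param ... named overrides of any default listed above (see the source of
#'   this function for the field names)
#' @return named list
#' @export
runConfig <- function(input_dir, output_dir, seed = 1L, ...) {
  fp <- function(f) file.path(input_dir, f)
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = seed,
    gff = fp("genes.gff3"), pep = fp("pep.fasta"), cds = fp("cds.fasta"),
    domain_hits = fp("domain_hits.tsv"),
    homolog_hits = fp("homolog_hits.tsv"),
    gene_order = fp("gene_order.tsv"),
    alignment = fp("family_aln.fasta"),
    ref_classes = fp("ref_classes.tsv"),
    tissue_fpkm = fp("tissue_fpkm.tsv"),
    infection_fpkm = fp("infection_fpkm.tsv"),
    vcf = fp("panel.vcf"), populations = fp("populations.tsv"),
    gene_bed = fp("genes.bed"),
    evalue_max = 1e-5, min_anchors = 5L, max_rank_gap = 25L,
    fold = 3, tau_min = 0.85, min_max_fpkm = 10, floor_fpkm = 1,
    up_thresh = 1, down_thresh = -1, min_peak_fpkm = 0.5, r_thresh = 0.5,
    lambda_rate = 6.1e-9,
    window_size = 20000L, window_step = 10000L,
    max_missing = 0.10, min_maf = 0.05, sweep_quantile = 0.05,
    bootstrap = 1000L,
    pop_wild = "wild", pop_cult = "cultivated"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown run-config fields: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' (TSV/Newick) to the output directory before the next starts, and returns
#' a report whose counts match the written files line for line. The
#' effective configuration is dumped to \code{run_config.tsv}.
#'
#' @param config from [runConfig()]
#' @return (invisibly) the report: a list with \code{family_size},
#'   \code{class_counts}, \code{duplication} (the [summarizeDuplication()]
#'   output), \code{expression_counts}, \code{response_counts},
#'   \code{pair_divergence}, \code{sweep} (threshold, n selected genes, ids)
#'   and \code{files} (paths written)
#' @export
runAll <- function(config) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  op <- function(f) file.path(out, f)
  utils::write.table(
    data.frame(parameter = names(config),
               value = vapply(config, function(x) paste(format(x), collapse = ","),
                              character(1))),
    op("run_config.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- character(0)

  ## catalog ------------------------------------------------------------------
  fc <- .stage("catalog", {
    catalog <- loadAnnotation(config$gff, config$pep, config$cds)
    hits <- readDomainHits(config$domain_hits)
    fc <- selectFamily(catalog, hits, config$evalue_max)
    writeCatalog(fc, op("catalog.tsv"))
    fc
  })
  files <- c(files, op("catalog.tsv"))
  members <- familyMembers(fc)

  ## phylogeny ----------------------------------------------------------------
  classes <- .stage("phylogeny", {
    aln <- readAlignedFasta(config$alignment)
    refs <- utils::read.delim(config$ref_classes, stringsAsFactors = FALSE)
    ref_labels <- stats::setNames(refs$class, refs$taxon)
    bt <- bootstrapPhylo(aln, config$bootstrap, config$seed)
    writeTree(bt$tree, op("tree.nwk"))
    cl <- assignClasses(bt$tree, ref_labels)
    utils::write.table(data.frame(taxon = names(cl), class = unname(cl)),
                       op("classes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cl
  })
  files <- c(files, op("tree.nwk"), op("classes.tsv"))

  ## duplication --------------------------------------------------------------
  dup <- .stage("duplication", {
    order <- readGeneOrder(config$gene_order)
    hh <- readHomologHits(config$homolog_hits)
    blocks <- detectBlocks(hh, order, config$min_anchors,
                           config$max_rank_gap, config$evalue_max)
    utils::write.table(blocksTable(blocks), op("blocks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tandem <- classifyTandem(order, members$gene_id)
    seg <- classifySegmental(blocks, members$gene_id)
    tx_of <- stats::setNames(members$transcript_id, members$gene_id)
    cds <- Biostrings::readDNAStringSet(config$cds)
    names(cds) <- sub("\\s.*$", "", names(cds))
    pairs <- seg$pairs
    if (nrow(pairs)) {
      kk <- lapply(seq_len(nrow(pairs)), function(i) {
        ca <- as.character(cds[[tx_of[pairs$gene_a[i]]]])
        cb <- as.character(cds[[tx_of[pairs$gene_b[i]]]])
        if (nchar(ca) != nchar(cb))
          return(list(ka = NA_real_, ks = NA_real_, omega = NA_real_))
        suppressWarnings(ng86KaKs(ca, cb))
      })
      pairs$ka <- vapply(kk, `[[`, numeric(1), "ka")
      pairs$ks <- vapply(kk, `[[`, numeric(1), "ks")
      pairs$omega <- vapply(kk, `[[`, numeric(1), "omega")
      pairs$wgd_bin <- as.character(assignWgdBin(pairs$ks))
      pairs$t_mya <- dateDuplication(pairs$ks, config$lambda_rate)
    }
    utils::write.table(pairs, op("pairs.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    summ <- summarizeDuplication(pairs$wgd_bin[!is.na(pairs$ks)],
                                 length(tandem), length(seg$segmental),
                                 nrow(members))
    list(blocks = blocks, tandem = tandem, segmental = seg$segmental,
         pairs = pairs, summary = summ)
  })
  files <- c(files, op("blocks.tsv"), op("pairs.tsv"))

  ## expression ---------------------------------------------------------------
  expr <- .stage("expression", {
    m <- readFpkm(config$tissue_fpkm)
    high <- classifyHigh(m, config$fold)
    spec <- lapply(seq_len(nrow(m)), function(i)
      tissueSpecificity(m[i, ], config$tau_min, config$min_max_fpkm))
    labels <- data.frame(
      gene_id = rownames(m),
      high = unname(high),
      tau = vapply(spec, `[[`, numeric(1), "tau"),
      top_tissue = vapply(spec, `[[`, character(1), "tissue"),
      specificity = vapply(spec, `[[`, character(1), "label"),
      activity = vapply(seq_len(nrow(m)), function(i)
        classifyInactive(m[i, ], config$floor_fpkm), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(labels, op("expression_labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tc <- readFpkm(config$infection_fpkm)
    resp <- lapply(seq_len(nrow(tc)), function(i)
      infectionResponse(tc[i, ], config$up_thresh, config$down_thresh,
                        config$min_peak_fpkm))
    l2 <- do.call(rbind, lapply(resp, `[[`, "l2fc"))
    colnames(l2) <- paste0("L_", colnames(tc)[-1L])
    response <- data.frame(gene_id = rownames(tc), round(l2, 3),
                           category = vapply(resp, `[[`, character(1),
                                             "category"),
                           stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(response, op("response.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pd <- character(0)
    pr <- dup$pairs
    if (nrow(pr)) {
      both <- pr$gene_a %in% rownames(m) & pr$gene_b %in% rownames(m)
      pd <- vapply(which(both), function(i)
        pairDivergence(m[pr$gene_a[i], ], m[pr$gene_b[i], ],
                       config$r_thresh)$label, character(1))
    }
    list(labels = labels, response = response, pair_labels = pd,
         pair_divergence = summarizePairDivergence(pd))
  })
  files <- c(files, op("expression_labels.tsv"), op("response.tsv"))

  ## selection ----------------------------------------------------------------
  sel <- .stage("selection", {
    panel <- readVcfPanel(config$vcf, config$populations)
    panel <- filterVariants(panel, config$max_missing, config$min_maf)
    genes <- readBedRegions(config$gene_bed)
    sites <- positionsOf(panel)
    chroms <- sort(unique(c(sites$chrom, genes$chrom)))
    windows <- lapply(stats::setNames(chroms, chroms), function(ch) {
      len <- max(sites$pos[sites$chrom == ch], genes$end[genes$chrom == ch])
      makeWindows(len, config$window_size, config$window_step)
    })
    pw <- windowPi(panel, config$pop_wild, windows)
    pc <- windowPi(panel, config$pop_cult, windows)
    scan <- ratioScan(pw, pc)
    base <- chromosomeBaseline(scan, genes)
    sw <- callSweeps(scan, genes, config$sweep_quantile)
    utils::write.table(sw$windows, op("windows.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report <- merge(base, sw$genes[, c("gene_id", "top5_selected")],
                    by = "gene_id", sort = TRUE)
    utils::write.table(report, op("sweep_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sel_genes <- sort(report$gene_id[report$top5_selected])
    if (length(sel_genes)) {
      regions <- genes[genes$gene_id %in% sel_genes,
                       c("chrom", "start", "end")]
      tr <- accessionTree(panel, regions)
      writeTree(tr, op("accessions.nwk"))
    }
    list(report = report, threshold = sw$threshold, selected = sel_genes)
  })
  files <- c(files, op("windows.tsv"), op("sweep_report.tsv"))

  report <- list(
    family_size = nrow(members),
    class_counts = table(classes),
    duplication = dup$summary,
    n_tandem = length(dup$tandem), n_segmental = length(dup$segmental),
    expression_counts = table(expr$labels$specificity),
    high_counts = table(expr$labels$high),
    response_counts = table(expr$response$category),
    pair_divergence = expr$pair_divergence,
    sweep = list(threshold = sel$threshold,
                 n_selected = length(sel$selected), genes = sel$selected),
    files = files
  )
  summary_kv <- data.frame(
    key = c("family_size", "n_collinear_pairs", "n_tandem", "n_segmental",
            "n_sweep_selected"),
    value = c(report$family_size, dup$summary$n_pairs, report$n_tandem,
              report$n_segmental, report$sweep$n_selected))
  utils::write.table(summary_kv, op("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Validate an input bundle without running it
#'
#' Per-file structural checks plus cross-file id consistency; reports
#' problems instead of throwing.
#'
#' @param config from [runConfig()]
#' @return data.frame \code{check ok detail}
#' @export
validateInputs <- function(config) {
  res <- list()
  add <- function(check, ok, detail = "") {
    res[[length(res) + 1L]] <<- data.frame(check = check, ok = ok,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }
  tryFile <- function(check, expr) {
    r <- tryCatch(list(ok = TRUE, val = expr, detail = ""),
                  error = function(e) list(ok = FALSE, val = NULL,
                                           detail = conditionMessage(e)),
                  warning = function(w) list(ok = TRUE, val = NULL,
                                             detail = conditionMessage(w)))
    add(check, r$ok, r$detail)
    r$val
  }
  catalog <- tryFile("gff3 parses", loadAnnotation(config$gff, config$pep,
                                                   config$cds))
  hits <- tryFile("domain hits parse", readDomainHits(config$domain_hits))
  if (!is.null(catalog) && !is.null(hits)) {
    miss <- setdiff(unique(hits$gene_id),
                    transcriptTable(catalog)$transcript_id)
    add("domain-hit ids known", !length(miss),
        if (length(miss)) paste("unknown:", paste(utils::head(miss, 5L),
                                                  collapse = ", ")) else "")
  }
  tryFile("homolog hits parse", readHomologHits(config$homolog_hits))
  tryFile("gene order parses", readGeneOrder(config$gene_order))
  fpkm <- tryFile("tissue FPKM parses", readFpkm(config$tissue_fpkm))
  if (!is.null(catalog) && !is.null(fpkm)) {
    gids <- unique(transcriptTable(catalog)$gene_id)
    unk <- setdiff(rownames(fpkm), gids)
    add("FPKM genes in catalog", !length(unk),
        if (length(unk)) paste("unknown:", paste(utils::head(unk, 5L),
                                                 collapse = ", ")) else "")
  }
  tryFile("infection FPKM parses", readFpkm(config$infection_fpkm))
  if (file.exists(config$vcf)) {
    vl <- readLines(config$vcf, warn = FALSE)
    body <- vl[!startsWith(vl, "#")]
    if (length(body)) {
      f <- strsplit(body, "\t", fixed = TRUE)
      ch <- vapply(f, `[[`, character(1), 1L)
      po <- as.integer(vapply(f, `[[`, character(1), 2L))
      bad <- unlist(lapply(split(po, ch), function(p) any(diff(p) <= 0)))
      add("VCF positions increasing", !any(bad),
          if (any(bad)) paste("non-increasing on:",
                              paste(names(bad)[bad], collapse = ", ")) else "")
    }
  } else add("VCF positions increasing", FALSE, "file missing")
  tryFile("population table parses", {
    p <- utils::read.delim(config$populations, stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "population") %in% names(p)))
    p
  })
  tryFile("gene BED parses", readBedRegions(config$gene_bed))
  do.call(rbind, res)
}
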