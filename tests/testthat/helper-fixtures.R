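# In-code fixture builders: tiny GFF3/FASTA bundles written to tempdir.

# genes: list(gene_id = list(chrom, start, strand, exon_lens, intron_len))
write_toy_gff <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (gid in names(genes)) {
    g <- genes[[gid]]
    s <- g$start
    ex <- matrix(0L, length(g$exon_lens), 2L)
    for (k in seq_along(g$exon_lens)) {
      ex[k, ] <- c(s, s + g$exon_lens[k] - 1L)
      s <- ex[k, 2L] + 1L + (g$intron_len %||% 100L)
    }
    tid <- paste0(gid, ".1")
    lines <- c(lines,
      paste(g$chrom, "test", "gene", ex[1, 1], ex[nrow(ex), 2], ".",
            g$strand, ".", sprintf("ID=%s", gid), sep = "\t"),
      paste(g$chrom, "test", "mRNA", ex[1, 1], ex[nrow(ex), 2], ".",
            g$strand, ".", sprintf("ID=%s;Parent=%s", tid, gid), sep = "\t"),
      paste(g$chrom, "test", "exon", ex[, 1], ex[, 2], ".", g$strand, ".",
            sprintf("ID=%s.e%d;Parent=%s", tid, seq_len(nrow(ex)), tid),
            sep = "\t"))
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  path
}

# a complete ORF of n codons total (ATG + body + TAA), deterministic
toy_orf <- function(n_codons, body_codon = "GGA") {
  paste(c("ATG", rep(body_codon, n_codons - 2L), "TAA"), collapse = "")
}

# domain-hit table granting the full three-domain architecture
full_domain_hits <- function(transcript_ids, e_value = 1e-30) {
  do.call(rbind, lapply(transcript_ids, function(t)
    data.frame(gene_id = t, domain = c("CuOx", "CuOx2", "CuOx3"),
               e_value = e_value, qstart = 1L, qend = 100L,
               stringsAsFactors = FALSE)))
}

extdata <- function(f) system.file("extdata", f, package = "famevo")
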