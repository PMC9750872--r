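# Deterministic fixture builders (no RNG).

# Enumerated unique protospacers: the i-th base-4 expansion over ACGT.
fixed_seqs <- function(n, width = 8) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1, function(i) {
    digits <- integer(width)
    for (p in seq_len(width)) {
      digits[p] <- i %% 4
      i <- i %/% 4
    }
    paste(bases[digits + 1], collapse = "")
  }, character(1))
}

# A tiny hand-built library: n_genes x n_tss groups of `spg` sgRNAs plus
# `n_nt` non-targeting controls.
toy_library <- function(n_genes = 2, spg = 3, n_nt = 5, n_tss = 1,
                        width = 8) {
  grid <- expand.grid(sg = seq_len(spg),
                      tss = sprintf("P%d", seq_len(n_tss)),
                      gene = sprintf("G%02d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  lib <- tibble::tibble(
    sgrna_id = c(sprintf("%s_%s_sg%d", grid$gene, grid$tss, grid$sg),
                 sprintf("NTC_sg%02d", seq_len(n_nt))),
    gene = c(grid$gene, rep(nontargeting_label(), n_nt)),
    tss = c(grid$tss, rep(nontargeting_label(), n_nt)),
    is_nontargeting = c(rep(FALSE, nrow(grid)), rep(TRUE, n_nt))
  )
  lib$sequence <- fixed_seqs(nrow(lib), width)
  lib[, c("sgrna_id", "sequence", "gene", "tss", "is_nontargeting")]
}

# Write a FASTQ file from a character vector of read sequences.
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads) > 0) {
    writeLines(paste(sprintf("@read%d", seq_along(reads)), reads, "+",
                     strrep("I", nchar(reads)), sep = "\n"), con)
  }
  invisible(path)
}
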