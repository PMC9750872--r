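#!/usr/bin/env Rscript

# Simulate a pooled CRISPRi chemical-genetic screen with known ground truth.
#
# Conditions mirror the screen design the scoring pipeline targets: 5 sgRNAs
# per gene, a non-targeting control set, a 6.1-doubling difference between
# the untreated and treated arms, ~500 reads/sgRNA, 5% of genes carrying a
# true sensitivity (rho) phenotype of either sign. Scaled to 2,000 genes so
# the whole analysis re-runs in about a minute.
#
# Writes results/screen_sim/: library.csv, counts.tsv (+ sample sidecar),
# truth_genes.tsv, truth_sgrnas.tsv.

suppressMessages(library(chemgenscreen))

out <- "results/screen_sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_genes = 2000, sgrnas_per_gene = 5, n_tss_per_gene = 1,
  n_nontargeting = 2000,
  frac_rho_hits = 0.05, frac_gamma_hits = 0.05,
  doublings_untreated = 10, doubling_difference = 6.1,
  mean_reads_per_sgrna = 500, dispersion = 0.05,
  seed = 2026L
)

lib <- simulate_library(cfg)
sim <- simulate_screen(lib, cfg)

write_library(lib, file.path(out, "library.csv"))
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_truth(sim$truth, file.path(out, "truth_genes.tsv"),
            file.path(out, "truth_sgrnas.tsv"))

truth <- unique(sim$truth$gene_truth[, c("gene", "true_rho")])
cat("Simulated screen:", nrow(lib), "sgRNAs,",
    sum(!lib$is_nontargeting), "targeting,",
    sum(lib$is_nontargeting), "non-targeting\n")
cat("Planted rho-hit genes:", sum(truth$true_rho != 0),
    "(", sum(truth$true_rho < 0), "sensitizing,",
    sum(truth$true_rho > 0), "protective )\n")
cat("Total depth per sample:", unique(colSums(sim$counts$counts)), "\n")
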