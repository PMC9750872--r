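#' Distribution specification for simulated effects and activities
#'
#' A small named-list spec used by [sim_config()] to describe how per-gene
#' phenotypes and per-sgRNA activities are drawn.
#'
#' Supported types:
#' * `"point"`: all draws equal `value`.
#' * `"normal"`: `rnorm(mean, sd)`.
#' * `"uniform"`: `runif(min, max)`.
#' * `"signed_uniform"`: magnitude `runif(min, max)`, sign negative with
#'   probability `prob_negative` (a two-sided effect mixture).
#' * `"beta"`: `rbeta(shape1, shape2)` (for activities on `[0, 1]`).
#'
#' @param type One of `"point"`, `"normal"`, `"uniform"`, `"signed_uniform"`,
#'   `"beta"`.
#' @param ... Parameters of the chosen type (see above).
#' @return A list with class `"effect_dist"`.
#' @examples
#' effect_dist("signed_uniform", min = 0.3, max = 0.6, prob_negative = 0.7)
#' @export
effect_dist <- function(type = c("point", "normal", "uniform",
                                 "signed_uniform", "beta"), ...) {
  type <- match.arg(type)
  spec <- c(list(type = type), list(...))
  defaults <- switch(type,
    point          = list(value = 0),
    normal         = list(mean = 0, sd = 1),
    uniform        = list(min = 0, max = 1),
    signed_uniform = list(min = 0.3, max = 0.6, prob_negative = 0.5),
    beta           = list(shape1 = 1, shape2 = 1)
  )
  for (nm in names(defaults)) {
    if (is.null(spec[[nm]])) spec[[nm]] <- defaults[[nm]]
  }
  structure(spec, class = "effect_dist")
}

# Draw n values from an effect_dist spec (uses the current RNG state).
draw_dist <- function(n, spec) {
  stopifnot(inherits(spec, "effect_dist"))
  switch(spec$type,
    point          = rep(spec$value, n),
    normal         = stats::rnorm(n, spec$mean, spec$sd),
    uniform        = stats::runif(n, spec$min, spec$max),
    signed_uniform = {
      mag  <- stats::runif(n, spec$min, spec$max)
      sgn  <- ifelse(stats::runif(n) < spec$prob_negative, -1, 1)
      mag * sgn
    },
    beta           = stats::rbeta(n, spec$shape1, spec$shape2)
  )
}

#' Configuration for a synthetic pooled CRISPRi chemical-genetic screen
#'
#' Bundles every knob of the screen simulator: library composition, the
#' distribution of true growth (gamma) and drug-sensitivity (rho) phenotypes,
#' per-sgRNA activity, growth/selection dynamics expressed in population
#' doublings, and the sequencing noise model.
#'
#' Phenotypes are log2 fitness effects per population doubling (gamma) or per
#' doubling difference between the treated and untreated arms (rho), matching
#' the units the scoring pipeline reports. The default `doubling_difference`
#' of 6.1 corresponds to the screen design the package targets; the untreated
#' arm's total doublings are free configuration.
#'
#' @param n_genes Number of targeted genes.
#' @param sgrnas_per_gene sgRNAs per gene per TSS (default 5).
#' @param n_tss_per_gene Transcription start sites per gene (default 1); each
#'   TSS gets its own group of `sgrnas_per_gene` sgRNAs, sharing the gene's
#'   true phenotype.
#' @param n_nontargeting Number of non-targeting control sgRNAs.
#' @param frac_rho_hits Fraction of genes with a true non-zero sensitivity
#'   (rho) phenotype.
#' @param frac_gamma_hits Fraction of genes with a true non-zero growth
#'   (gamma) phenotype.
#' @param rho_effect_dist,gamma_effect_dist [effect_dist()] specs for the true
#'   phenotypes of hit genes (non-hit genes are exactly 0).
#' @param activity_dist [effect_dist()] spec on `[0, 1]` for per-sgRNA
#'   efficacy; an sgRNA's realized effect is `activity * gene effect`.
#' @param doublings_untreated Total population doublings of the untreated arm
#'   from t0 (D_u).
#' @param doubling_difference Doubling difference between untreated and
#'   treated arms (delta-D; default 6.1).
#' @param mean_reads_per_sgrna Target sequencing coverage per sgRNA.
#' @param dispersion Count overdispersion: approximately the excess squared
#'   coefficient of variation of a typical sgRNA's frequency under the
#'   Dirichlet-multinomial noise model; `0` gives a pure multinomial.
#' @param t0_sigma Log-normal sdlog of the t0 library representation skew.
#' @param protospacer_length Protospacer length in nt (default 20).
#' @param seed Integer seed; the same seed and config give byte-identical
#'   outputs.
#' @return A list with class `"sim_config"`.
#' @seealso [simulate_library()], [simulate_screen()]
#' @export
sim_config <- function(n_genes = 100,
                       sgrnas_per_gene = 5,
                       n_tss_per_gene = 1,
                       n_nontargeting = 200,
                       frac_rho_hits = 0.05,
                       frac_gamma_hits = 0.05,
                       rho_effect_dist = effect_dist("signed_uniform",
                                                     min = 0.3, max = 0.6,
                                                     prob_negative = 0.7),
                       gamma_effect_dist = effect_dist("signed_uniform",
                                                       min = 0.05, max = 0.2,
                                                       prob_negative = 0.9),
                       activity_dist = effect_dist("uniform",
                                                   min = 0.7, max = 1),
                       doublings_untreated = 10,
                       doubling_difference = 6.1,
                       mean_reads_per_sgrna = 500,
                       dispersion = 0.05,
                       t0_sigma = 0.5,
                       protospacer_length = 20,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    sgrnas_per_gene = as.integer(sgrnas_per_gene),
    n_tss_per_gene = as.integer(n_tss_per_gene),
    n_nontargeting = as.integer(n_nontargeting),
    frac_rho_hits = frac_rho_hits,
    frac_gamma_hits = frac_gamma_hits,
    rho_effect_dist = rho_effect_dist,
    gamma_effect_dist = gamma_effect_dist,
    activity_dist = activity_dist,
    doublings_untreated = doublings_untreated,
    doubling_difference = doubling_difference,
    mean_reads_per_sgrna = mean_reads_per_sgrna,
    dispersion = dispersion,
    t0_sigma = t0_sigma,
    protospacer_length = as.integer(protospacer_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos_int <- c("n_genes", "sgrnas_per_gene", "n_tss_per_gene",
               "n_nontargeting", "protospacer_length")
  for (nm in pos_int) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("`", nm, "` must be a single positive integer", call. = FALSE)
    }
  }
  for (nm in c("frac_rho_hits", "frac_gamma_hits")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("doublings_untreated", "doubling_difference",
               "mean_reads_per_sgrna")) {
    if (cfg[[nm]] <= 0) stop("`", nm, "` must be strictly positive",
                             call. = FALSE)
  }
  if (cfg$dispersion < 0) stop("`dispersion` must be non-negative",
                               call. = FALSE)
  if (cfg$t0_sigma < 0) stop("`t0_sigma` must be non-negative", call. = FALSE)
  invisible(cfg)
}

# Deterministic sub-seed derivation: one global seed, fixed offsets per
# random stage, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
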