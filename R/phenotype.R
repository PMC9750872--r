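#' Parameters for phenotype computation
#'
#' @param pseudocount Positive real added to every count before frequency
#'   computation (default 10); guarantees finite log-ratios at zero counts.
#' @param min_reads Optional t0 count threshold (default 0 = off); sgRNAs
#'   below it are flagged `filtered` and carry `NA` phenotypes, never 0.
#' @param doublings_untreated Total doublings of the untreated population
#'   from t0 (D_u), the normalizer of the growth phenotype gamma.
#' @param doubling_difference Doubling difference between untreated and
#'   treated populations (delta-D, default 6.1), the normalizer of the
#'   sensitivity phenotype rho.
#' @return A list with class `"phenotype_params"`.
#' @export
phenotype_params <- function(pseudocount = 10, min_reads = 0,
                             doublings_untreated = NULL,
                             doubling_difference = 6.1) {
  if (pseudocount <= 0) stop("`pseudocount` must be > 0", call. = FALSE)
  if (min_reads < 0) stop("`min_reads` must be >= 0", call. = FALSE)
  for (nm in c("doublings_untreated", "doubling_difference")) {
    v <- get(nm)
    if (!is.null(v) && v <= 0) stop("`", nm, "` must be > 0", call. = FALSE)
  }
  structure(list(pseudocount = pseudocount, min_reads = min_reads,
                 doublings_untreated = doublings_untreated,
                 doubling_difference = doubling_difference),
            class = "phenotype_params")
}

#' Per-sgRNA log2 enrichment between two samples
#'
#' `e_i = log2(f_i(A) / f_i(B))` where
#' `f_i(S) = (c_i(S) + pseudocount) / sum_j (c_j(S) + pseudocount)`.
#' Invariant to uniform rescaling of either sample's total depth.
#'
#' @param counts_a,counts_b Aligned count vectors for samples A and B.
#' @param pseudocount Positive pseudocount.
#' @return Numeric vector of log2 enrichments.
#' @export
log2_enrichment <- function(counts_a, counts_b, pseudocount = 10) {
  stopifnot(length(counts_a) == length(counts_b), pseudocount > 0)
  fa <- (counts_a + pseudocount) / sum(counts_a + pseudocount)
  fb <- (counts_b + pseudocount) / sum(counts_b + pseudocount)
  log2(fa / fb)
}

#' Compute growth (gamma) and sensitivity (rho) phenotypes
#'
#' For each sgRNA, the raw log2 enrichments untreated-vs-t0 and
#' treated-vs-untreated are computed with [log2_enrichment()], the median
#' over all non-targeting sgRNAs is subtracted, and the result is divided by
#' the relevant number of population doublings:
#' `gamma_i = (e_i(untreated, t0) - median_NT e) / D_u` and
#' `rho_i   = (e_i(treated, untreated) - median_NT e) / delta_D`.
#' Negative rho means knockdown sensitizes to the drug (depletion under
#' treatment); the non-targeting median of both phenotypes is 0 by
#' construction.
#'
#' When a role has several replicate samples, phenotypes are computed per
#' replicate pair (index-matched, recycling the first partner) and averaged;
#' the residual non-targeting median of the average is subtracted so the
#' zero-median invariant holds exactly. Per-replicate phenotype matrices are
#' kept in the attributes `"gamma_reps"` / `"rho_reps"`.
#'
#' @param counts A [count_table()] with at least one sample per role
#'   (`t0`, `untreated`, `treated`; `treated` optional if only gamma is
#'   wanted).
#' @param library The matching library tibble (supplies gene/TSS grouping and
#'   the non-targeting flag).
#' @param params [phenotype_params()]. `doublings_untreated` /
#'   `doubling_difference` default to the count table's sample metadata when
#'   not set.
#' @return A tibble with columns `sgrna_id`, `gene`, `tss`,
#'   `is_nontargeting`, `e_ut_t0`, `e_tr_ut`, `gamma`, `rho`, `filtered`.
#' @export
compute_phenotypes <- function(counts, library, params = phenotype_params()) {
  stopifnot(inherits(counts, "count_table"),
            inherits(params, "phenotype_params"))
  validate_library(library)
  lib <- library
  if (!setequal(rownames(counts$counts), lib$sgrna_id)) {
    stop("count table rows do not match library sgrna_ids", call. = FALSE)
  }
  mat <- counts$counts[lib$sgrna_id, , drop = FALSE]
  nt <- lib$is_nontargeting

  t0s <- samples_by_role(counts, "t0")
  unt <- samples_by_role(counts, "untreated")
  trt <- samples_by_role(counts, "treated")
  if (length(t0s) == 0 || length(unt) == 0) {
    stop("phenotypes need at least one t0 and one untreated sample",
         call. = FALSE)
  }

  du <- params$doublings_untreated %||% infer_doublings(counts, "untreated")
  if (is.null(du)) {
    stop("`doublings_untreated` not set and not available from sample ",
         "metadata; gamma needs an explicit normalizer", call. = FALSE)
  }

  filtered <- rep(FALSE, nrow(lib))
  if (params$min_reads > 0) {
    t0_min <- apply(mat[, t0s, drop = FALSE], 1, min)
    filtered <- t0_min < params$min_reads
  }

  pair_enrich <- function(num_samples, den_samples) {
    n_rep <- max(length(num_samples), length(den_samples))
    vapply(seq_len(n_rep), function(r) {
      a <- num_samples[min(r, length(num_samples))]
      b <- den_samples[min(r, length(den_samples))]
      log2_enrichment(mat[, a], mat[, b], params$pseudocount)
    }, numeric(nrow(mat)))
  }
  normalize <- function(e_mat, divisor) {
    ph <- sweep(e_mat, 2, apply(e_mat[nt & !filtered, , drop = FALSE], 2,
                                stats::median)) / divisor
    avg <- rowMeans(ph)
    avg - stats::median(avg[nt & !filtered])
  }

  e_ut <- pair_enrich(unt, t0s)
  gamma <- normalize(e_ut, du)

  if (length(trt) > 0) {
    dd <- params$doubling_difference %||%
      attr(counts, "doubling_difference") %||%
      stop("`doubling_difference` not set", call. = FALSE)
    e_tr <- pair_enrich(trt, unt)
    rho <- normalize(e_tr, dd)
  } else {
    e_tr <- matrix(NA_real_, nrow(mat), 1)
    rho <- rep(NA_real_, nrow(mat))
  }

  out <- tibble::tibble(
    sgrna_id = lib$sgrna_id,
    gene = lib$gene,
    tss = lib$tss,
    is_nontargeting = nt,
    e_ut_t0 = rowMeans(e_ut),
    e_tr_ut = rowMeans(e_tr),
    gamma = ifelse(filtered, NA_real_, gamma),
    rho = ifelse(filtered, NA_real_, rho),
    filtered = filtered
  )
  attr(out, "params") <- params
  attr(out, "gamma_reps") <- e_ut
  attr(out, "rho_reps") <- e_tr
  out
}

infer_doublings <- function(counts, role) {
  d <- counts$samples$doublings[counts$samples$role == role]
  if (length(d) == 0 || any(is.na(d))) NULL else mean(d)
}

#' @describeIn compute_phenotypes Gamma-only convenience wrapper (no treated
#'   sample required).
#' @export
compute_gamma <- function(counts, library, params = phenotype_params()) {
  ph <- compute_phenotypes(counts, library, params)
  ph[, c("sgrna_id", "gene", "tss", "is_nontargeting", "e_ut_t0", "gamma",
         "filtered")]
}

#' @describeIn compute_phenotypes Rho-only convenience wrapper.
#' @export
compute_rho <- function(counts, library, params = phenotype_params()) {
  ph <- compute_phenotypes(counts, library, params)
  ph[, c("sgrna_id", "gene", "tss", "is_nontargeting", "e_tr_ut", "rho",
         "filtered")]
}

#' BFP enrichment statistic for individual knockdown re-tests
#'
#' In an internally controlled re-test, sgRNA-expressing cells are marked by
#' BFP and their population fraction is followed over time by flow cytometry.
#' Enrichment at day d is `fraction(d) / fraction(0)` per condition; relative
#' enrichment divides a condition's enrichment by the reference condition's.
#' A relative enrichment below 1 under drug means the knockdown sensitizes.
#'
#' @param data Tibble with columns `condition`, `day`, `fraction` (in (0, 1);
#'   replicates are averaged per condition/day first). Every condition must
#'   include day 0.
#' @param reference Condition used as the denominator of the relative
#'   enrichment (default `"untreated"`; must be present in `data`).
#' @return Tibble with `condition`, `day`, `fraction`, `enrichment`,
#'   `relative_enrichment`.
#' @export
retest_enrichment <- function(data, reference = "untreated") {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("condition", "day", "fraction") %in% names(data)))
  if (any(data$fraction <= 0 | data$fraction >= 1)) {
    stop("BFP fractions must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!reference %in% data$condition) {
    stop("reference condition `", reference, "` not present", call. = FALSE)
  }
  avg <- data |>
    dplyr::group_by(.data$condition, .data$day) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  base <- avg[avg$day == 0, ]
  if (!setequal(base$condition, unique(avg$condition))) {
    stop("every condition needs a day-0 baseline", call. = FALSE)
  }
  avg$enrichment <- avg$fraction /
    base$fraction[match(avg$condition, base$condition)]
  ref <- avg[avg$condition == reference, ]
  avg$relative_enrichment <- avg$enrichment /
    ref$enrichment[match(avg$day, ref$day)]
  avg
}
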