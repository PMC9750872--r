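test_that("log2 enrichment matches hand arithmetic and its invariances", {
  expect_equal(log2_enrichment(c(5, 9, 2), c(5, 9, 2)), c(0, 0, 0))

  # (30,10) vs (10,30) with pseudocount 10: f(A)=(2/3,1/3), f(B)=(1/3,2/3).
  expect_equal(log2_enrichment(c(30, 10), c(10, 30), pseudocount = 10),
               c(1, -1))

  # Frequency-based, so uniform depth rescaling cancels (up to the
  # unscaled pseudocount, negligible at these counts).
  a <- c(4000, 1000, 2500)
  b <- c(1200, 3600, 2100)
  expect_equal(log2_enrichment(2 * a, b), log2_enrichment(a, b),
               tolerance = 1e-2)
  expect_error(phenotype_params(pseudocount = 0), "pseudocount")
})

# Exact hand-built screens: 1 targeting + 2 non-targeting sgRNAs, pseudocount
# 10. Frequencies and medians work out to round numbers.
hand_counts <- function(t0, unt, trt) {
  lib <- toy_library(n_genes = 1, spg = 1, n_nt = 2)
  mat <- cbind(t0 = t0, untreated = unt, treated = trt)
  rownames(mat) <- lib$sgrna_id
  list(lib = lib,
       ct = count_table(mat, tibble::tibble(
         name = c("t0", "untreated", "treated"),
         role = c("t0", "untreated", "treated"))))
}

test_that("gamma matches hand arithmetic and is zero on identity counts", {
  # untreated (70,30,30)+10 -> f=(.5,.25,.25); t0 uniform -> e=(log2 1.5,
  # log2 .75, log2 .75); NT median subtraction leaves exactly 1 for the
  # targeting sgRNA; D_u = 10 gives gamma = 0.1.
  h <- hand_counts(t0 = c(10, 10, 10), unt = c(70, 30, 30),
                   trt = c(70, 30, 30))
  ph <- compute_phenotypes(h$ct, h$lib,
                           phenotype_params(doublings_untreated = 10))
  expect_equal(ph$gamma[!ph$is_nontargeting], 0.1)
  expect_equal(ph$gamma[ph$is_nontargeting], c(0, 0))

  same <- hand_counts(c(7, 9, 11), c(7, 9, 11), c(7, 9, 11))
  ph0 <- compute_phenotypes(same$ct, same$lib,
                            phenotype_params(doublings_untreated = 10))
  expect_true(all(ph0$gamma == 0))
  expect_true(all(ph0$rho == 0))
})

test_that("rho matches hand arithmetic with the 6.1 doubling difference", {
  # treated (15,40,40)+10 vs untreated (90,40,40)+10: e_t - median_NT =
  # log2(0.25) = -2; rho = -2 / 6.1. Depletion under drug => rho < 0.
  h <- hand_counts(t0 = c(10, 10, 10), unt = c(90, 40, 40),
                   trt = c(15, 40, 40))
  ph <- compute_phenotypes(h$ct, h$lib,
                           phenotype_params(doublings_untreated = 10,
                                            doubling_difference = 6.1))
  expect_equal(ph$rho[!ph$is_nontargeting], -2 / 6.1)
  expect_lt(ph$rho[!ph$is_nontargeting], 0)
  expect_equal(ph$rho[ph$is_nontargeting], c(0, 0))
})

test_that("non-targeting medians of gamma and rho are exactly zero", {
  cfg <- sim_config(n_genes = 15, n_nontargeting = 31, seed = 8)
  lib <- simulate_library(cfg)
  sim <- simulate_screen(lib, cfg)
  ph <- compute_phenotypes(sim$counts, lib,
                           phenotype_params(doublings_untreated = 10))
  expect_identical(median(ph$gamma[ph$is_nontargeting]), 0)
  expect_identical(median(ph$rho[ph$is_nontargeting]), 0)
})

test_that("phenotypes refuse to run without explicit doubling normalizers", {
  h <- hand_counts(c(10, 10, 10), c(20, 10, 10), c(10, 10, 10))
  h$ct$samples$doublings <- NA_real_
  attr(h$ct, "doubling_difference") <- NULL
  expect_error(compute_phenotypes(h$ct, h$lib, phenotype_params()),
               "doublings_untreated")
})

test_that("min_reads filtering marks sgRNAs missing, never zero, and leaves survivors untouched", {
  cfg <- sim_config(n_genes = 10, n_nontargeting = 20,
                    mean_reads_per_sgrna = 30, t0_sigma = 1.2, seed = 12)
  lib <- simulate_library(cfg)
  sim <- simulate_screen(lib, cfg)
  base <- compute_phenotypes(sim$counts, lib,
                             phenotype_params(doublings_untreated = 10))
  filt <- compute_phenotypes(sim$counts, lib,
                             phenotype_params(doublings_untreated = 10,
                                              min_reads = 20))
  expect_true(any(filt$filtered))
  expect_true(all(is.na(filt$rho[filt$filtered])))
  expect_true(all(is.na(filt$gamma[filt$filtered])))
  # Raw enrichments are computed before filtering and never edited.
  expect_equal(filt$e_ut_t0, base$e_ut_t0)
  expect_equal(filt$e_tr_ut, base$e_tr_ut)
  surv <- !filt$filtered
  expect_equal(sign(filt$e_tr_ut[surv]), sign(base$e_tr_ut[surv]))
})

test_that("replicate samples are averaged per replicate", {
  lib <- toy_library(n_genes = 2, spg = 2, n_nt = 5)
  n <- nrow(lib)
  set.seed(31)
  mat <- matrix(rpois(n * 4, 200), ncol = 4,
                dimnames = list(lib$sgrna_id,
                                c("t0", "unt_a", "unt_b", "trt")))
  ct <- count_table(mat, tibble::tibble(
    name = colnames(mat),
    role = c("t0", "untreated", "untreated", "treated")))
  ph <- compute_phenotypes(ct, lib,
                           phenotype_params(doublings_untreated = 10))
  reps <- attr(ph, "gamma_reps")
  expect_equal(ncol(reps), 2)
  expect_equal(ph$e_ut_t0, rowMeans(reps))
  expect_identical(median(ph$gamma[ph$is_nontargeting]), 0)
})

test_that("BFP re-test enrichment follows the ratio contracts", {
  flat <- tibble::tibble(condition = rep(c("untreated", "treated"), each = 3),
                         day = rep(c(0, 3, 6), 2),
                         fraction = 0.5)
  out <- retest_enrichment(flat)
  expect_true(all(out$enrichment == 1))
  expect_true(all(out$relative_enrichment == 1))

  dep <- tibble::tibble(condition = rep(c("untreated", "treated"), each = 2),
                        day = rep(c(0, 5), 2),
                        fraction = c(0.5, 0.5, 0.5, 0.25))
  out <- retest_enrichment(dep)
  expect_equal(out$relative_enrichment[out$condition == "treated" &
                                         out$day == 5], 0.5)

  # Swapping which condition is the reference inverts the ratio.
  swapped <- retest_enrichment(dep, reference = "treated")
  expect_equal(swapped$relative_enrichment[swapped$condition == "untreated" &
                                             swapped$day == 5], 2)

  bad <- dep
  bad$fraction[1] <- 1
  expect_error(retest_enrichment(bad), "strictly in")
})
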