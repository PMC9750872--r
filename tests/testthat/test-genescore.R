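test_that("top-3-by-absolute-value collapse matches hand arithmetic", {
  expect_equal(collapse_gene(c(0.1, 0.2, 0.3)), 0.2)
  expect_equal(collapse_gene(c(-0.50, 0.40, -0.45, 0.01, -0.02)),
               mean(c(-0.50, -0.45, 0.40)))
  expect_equal(collapse_gene(c(0, 0, 0, 0, 0)), 0)
  expect_equal(collapse_gene(c(0.4, 0.2)), 0.3)  # fewer than k: mean of all
  # |.| ties broken lexicographically by id, so the result is deterministic.
  expect_equal(collapse_gene(c(0.5, -0.5, 0.5, -0.5),
                             ids = c("d", "c", "b", "a")),
               mean(c(-0.5, 0.5, -0.5)))
})

test_that("Mann-Whitney p is exact for small tie-free groups", {
  # Complete separation at 3 vs 3: 2/20 arrangements are as extreme.
  p <- mann_whitney_p(c(2.0, 2.1, 2.2), c(-0.1, 0.0, 0.1))
  expect_equal(p, 0.1)
  expect_equal(p, mw_enum_p(c(2.0, 2.1, 2.2), c(-0.1, 0.0, 0.1)))

  # Fully tied groups carry no evidence.
  expect_equal(mann_whitney_p(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(mann_whitney_p(numeric(0), c(1)), "non-empty")
})

test_that("normal approximation tracks the exact null for small groups", {
  # Exhaustive sweep (oracle): the continuity-corrected normal approximation
  # differs from the exact p by at most 0.0375 over all tie-free
  # configurations with group sizes 3-8 (worst at 3 vs 3), and by at most
  # 0.0173 once both groups have >= 5 observations.
  set.seed(99)
  for (i in 1:60) {
    m <- sample(3:8, 1)
    n <- sample(3:8, 1)
    x <- rnorm(m)
    y <- rnorm(n)
    exact <- mann_whitney_p(x, y)
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    gap <- abs(exact - min(approx, 1))
    expect_lt(gap, 0.038)
    if (m >= 5 && n >= 5) expect_lt(gap, 0.02)
  }
})

test_that("negative-control pseudo-genes are valid, deterministic and distinct", {
  lib <- toy_library(n_genes = 4, spg = 5, n_nt = 10)
  ncg <- make_negative_control_genes(lib, n_pseudo = 4, size = 5, seed = 2)
  expect_equal(dplyr::n_distinct(ncg$gene), 4)
  expect_true(all(table(ncg$gene) == 5))
  expect_true(all(ncg$sgrna_id %in% lib$sgrna_id[lib$is_nontargeting]))
  # No within-group duplicates, no duplicated member sets.
  sets <- tapply(ncg$sgrna_id, ncg$gene, function(x)
    paste(sort(x), collapse = ";"))
  expect_false(anyDuplicated(sets) > 0)
  expect_true(all(tapply(ncg$sgrna_id, ncg$gene,
                         function(x) !anyDuplicated(x))))

  expect_identical(make_negative_control_genes(lib, 4, 5, seed = 2), ncg)
  expect_error(make_negative_control_genes(lib, 2, size = 11), "exceeds")

  # Defaults: as many pseudo-genes as real gene/TSS groups, modal size.
  defaults <- make_negative_control_genes(lib, seed = 1)
  expect_equal(dplyr::n_distinct(defaults$gene), 4)
  expect_equal(attr(defaults, "size"), 5L)
})

test_that("pseudo-gene membership is approximately uniform over the non-targeting set", {
  lib <- toy_library(n_genes = 2, spg = 5, n_nt = 100)
  ncg <- make_negative_control_genes(lib, n_pseudo = 10000, size = 5,
                                     seed = 7)
  usage <- table(factor(ncg$sgrna_id,
                        levels = lib$sgrna_id[lib$is_nontargeting]))
  p <- chisq.test(as.vector(usage))$p.value
  expect_gt(p, 1e-4)
})

# A phenotype-table stub: `n_nt` non-targeting sgRNAs with given values plus
# per-gene targeting groups.
phen_stub <- function(gene_values, nt_values) {
  genes <- names(gene_values)
  tibble::tibble(
    sgrna_id = c(sprintf("NT_sg%03d", seq_along(nt_values)),
                 unlist(lapply(genes, function(g)
                   sprintf("%s_P1_sg%d", g, seq_along(gene_values[[g]]))))),
    gene = c(rep(nontargeting_label(), length(nt_values)),
             rep(genes, lengths(gene_values))),
    tss = c(rep(nontargeting_label(), length(nt_values)),
            rep("P1", sum(lengths(gene_values)))),
    is_nontargeting = c(rep(TRUE, length(nt_values)),
                        rep(FALSE, sum(lengths(gene_values)))),
    rho = c(nt_values, unlist(gene_values)),
    filtered = FALSE
  )
}

stub_library <- function(phen) {
  lib <- phen[, c("sgrna_id", "gene", "tss", "is_nontargeting")]
  lib$sequence <- fixed_seqs(nrow(lib), 10)
  lib
}

test_that("a null screen calls no hits and z-scores stay near zero", {
  set.seed(5)
  phen <- phen_stub(
    gene_values = setNames(replicate(20, rnorm(5, 0, 0.01),
                                     simplify = FALSE),
                           sprintf("G%02d", 1:20)),
    nt_values = rnorm(100, 0, 0.01)
  )
  ncg <- make_negative_control_genes(stub_library(phen), seed = 3)
  sc <- score_genes(phen, ncg)
  expect_false(any(sc$is_hit))
  expect_lt(max(abs(sc$z[!sc$is_negative_control])), 7)
  expect_true(all(sc$direction == "none"))
})

test_that("discriminant score is recomputable, monotone, and thresholded at >= 7", {
  set.seed(6)
  phen <- phen_stub(
    gene_values = c(list(HIT = rep(-0.5, 5) + rnorm(5, 0, 0.01)),
                    setNames(replicate(19, rnorm(5, 0, 0.02),
                                       simplify = FALSE),
                             sprintf("G%02d", 1:19))),
    nt_values = rnorm(100, 0, 0.02)
  )
  ncg <- make_negative_control_genes(stub_library(phen), seed = 3)
  sc <- score_genes(phen, ncg)
  expect_equal(sc$discriminant, abs(sc$z) * (-log10(sc$p_value)))
  expect_equal(sc$is_hit, sc$discriminant >= 7)
  hit <- sc[sc$gene == "HIT", ]
  expect_true(hit$is_hit)
  expect_equal(hit$direction, "sensitizing")

  # Monotone in |z| at fixed p and in -log10 p at fixed z.
  zs <- seq(0, 5, by = 0.5)
  expect_true(all(diff(abs(zs) * -log10(0.01)) >= 0))
  ps <- 10^seq(-1, -8)
  expect_true(all(diff(3 * -log10(ps)) >= 0))
})

test_that("gene scores are invariant to sgRNA row order", {
  set.seed(7)
  phen <- phen_stub(
    gene_values = setNames(replicate(10, rnorm(5, 0, 0.3),
                                     simplify = FALSE),
                           sprintf("G%02d", 1:10)),
    nt_values = rnorm(60, 0, 0.1)
  )
  ncg <- make_negative_control_genes(stub_library(phen), seed = 4)
  a <- score_genes(phen, ncg)
  b <- score_genes(phen[sample(nrow(phen)), ], ncg)
  expect_equal(a, b)
})

test_that("TSS collapse keeps the lowest-p row verbatim with stated tie-breaks", {
  row <- function(gene, tss, p, phen) {
    tibble::tibble(gene = gene, tss = tss, phenotype = phen, p_value = p,
                   n_sgrnas_used = 5L, is_negative_control = FALSE,
                   z = phen / 0.1, discriminant = abs(phen / 0.1) * -log10(p),
                   is_hit = FALSE, direction = "none", bh_fdr = NA_real_)
  }
  scores <- dplyr::bind_rows(
    row("A", "P1", 0.01, -0.2), row("A", "P2", 0.2, -0.5),
    row("B", "P1", 0.05, 0.3), row("B", "P2", 0.05, 0.1),
    row("C", "P1", 0.5, 0.05)
  )
  out <- collapse_tss(scores)
  expect_equal(nrow(out), 3)
  expect_equal(out$tss[out$gene == "A"], "P1")
  expect_equal(out$phenotype[out$gene == "A"], -0.2)
  expect_equal(out$phenotype[out$gene == "B"], 0.3)  # tie: larger |phenotype|
  expect_equal(out$phenotype[out$gene == "C"], 0.05) # single TSS unchanged
})

test_that("volcano export reproduces the score table bit for bit", {
  set.seed(8)
  phen <- phen_stub(
    gene_values = setNames(replicate(8, rnorm(5, 0, 0.2),
                                     simplify = FALSE),
                           sprintf("G%02d", 1:8)),
    nt_values = rnorm(50, 0, 0.1)
  )
  ncg <- make_negative_control_genes(stub_library(phen), seed = 5)
  sc <- score_genes(phen, ncg)
  dir <- withr::local_tempdir()
  dat <- export_volcano(sc, file.path(dir, "volcano.tsv"))
  expect_identical(dat$phenotype, sc$phenotype)
  expect_identical(dat$neg_log10_p, -log10(sc$p_value))
})
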