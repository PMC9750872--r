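rec <- function(line, gene, class, cadd = NA_real_) {
  tibble::tibble(cell_line = line, gene = gene, variant_class = class,
                 cadd_phred = cadd)
}

test_that("variant filtering applies the class and CADD rules", {
  records <- dplyr::bind_rows(
    rec("X", "G1", "Missense_Mutation", 15.0),
    rec("X", "G2", "Missense_Mutation", 14.9),
    rec("X", "G3", "In_Frame_Del"),
    rec("X", "G4", "In_Frame_Ins"),
    rec("X", "G5", "Silent", 30),
    rec("X", "G6", "Intron", 22),
    rec("X", "G7", "Frame_Shift_Ins"),
    rec("X", "G8", "Nonsense_Mutation", 35)
  )
  kept <- filter_mutations(records)
  expect_setequal(kept$gene, c("G1", "G3", "G7", "G8"))

  # The threshold is inclusive and configurable.
  expect_true("G2" %in% filter_mutations(records, cadd_min = 14)$gene)
  expect_equal(nrow(filter_mutations(records[0, ])), 0)

  # SNVs without CADD scores are dropped with a warning.
  expect_warning(out <- filter_mutations(rec("X", "G9",
                                             "Missense_Mutation")),
                 "without a CADD")
  expect_equal(nrow(out), 0)

  # Unknown classes: warn-and-drop by default, error under strict.
  expect_warning(filter_mutations(rec("X", "G1", "Weird_Class", 20)),
                 "unknown variant class")
  expect_error(filter_mutations(rec("X", "G1", "Weird_Class", 20),
                                strict = TRUE),
               "unknown variant class")
})

test_that("filtering retained records again changes nothing", {
  set.seed(21)
  classes <- default_variant_class_map()$raw
  records <- tibble::tibble(
    cell_line = sample(sprintf("CL%02d", 1:10), 200, replace = TRUE),
    gene = sample(sprintf("G%02d", 1:20), 200, replace = TRUE),
    variant_class = sample(classes, 200, replace = TRUE),
    cadd_phred = runif(200, 0, 40)
  )
  once <- filter_mutations(records)
  twice <- filter_mutations(once)
  expect_equal(once, twice)
})

test_that("the mutation matrix is binary with the counted-once rule", {
  records <- dplyr::bind_rows(
    rec("X", "G1", "snv_missense", 20),
    rec("X", "G1", "snv_nonsense", 30),
    rec("X", "G1", "frameshift_indel"),
    rec("Z", "G2", "snv_missense", 25)
  )
  mat <- build_matrix(records, cell_lines = c("X", "Y", "Z"))
  expect_equal(mat["G1", "X"], 1L)          # 3 mutations count once
  expect_true(all(mat[, "Y"] == 0L))        # no records: all-zero column
  expect_equal(mat["G2", "Z"], 1L)
  expect_equal(mat["G2", "X"], 0L)
  expect_true(all(mat %in% 0:1))

  expect_error(build_matrix(rec("OUTSIDE", "G1", "snv_missense", 20),
                            cell_lines = c("X")),
               "outside the universe")
  expect_warning(m2 <- build_matrix(rec("OUTSIDE", "G1", "snv_missense", 20),
                                    cell_lines = c("X"),
                                    unknown_line = "drop"),
                 "dropped")
  expect_equal(nrow(m2), 0)
})

test_that("per-gene Wilcoxon association matches the enumeration oracle", {
  mat <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), nrow = 1,
                dimnames = list("G1", sprintf("CL%d", 1:6)))
  ic50 <- c(CL1 = 0.05, CL2 = 0.07, CL3 = 0.10,
            CL4 = 0.40, CL5 = 0.50, CL6 = 0.60)
  res <- wilcoxon_association(mat, ic50)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, mw_enum_p(ic50[1:3], ic50[4:6]))
  expect_equal(res$median_mutant, 0.07)
  expect_equal(res$median_wildtype, 0.50)
  expect_equal(res$n_mutant + res$n_wildtype, 6L)

  # Identical value multisets in both groups carry no evidence.
  mat2 <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), nrow = 1,
                 dimnames = list("G1", sprintf("CL%d", 1:6)))
  same <- c(CL1 = 1, CL2 = 2, CL3 = 3, CL4 = 1, CL5 = 2, CL6 = 3)
  expect_equal(wilcoxon_association(mat2, same)$p_value, 1)

  # Below min_group the gene is reported untestable, not dropped.
  mat3 <- matrix(c(1L, 0L, 0L, 0L, 0L, 0L), nrow = 1,
                 dimnames = list("G1", sprintf("CL%d", 1:6)))
  res3 <- wilcoxon_association(mat3, ic50, min_group = 2)
  expect_true(is.na(res3$p_value))
  expect_equal(res3$n_mutant, 1L)
})

test_that("association p-values are invariant to monotone IC50 transforms", {
  coh <- simulate_mutation_cohort(n_lines = 20, n_genes = 30, seed = 4)
  a <- wilcoxon_association(coh$matrix, coh$ic50)
  b <- wilcoxon_association(coh$matrix, log10(coh$ic50))
  expect_equal(a$p_value, b$p_value)
})

test_that("gene-set association unions mutant lines and gains power from spread effects", {
  mat <- matrix(0L, nrow = 2, ncol = 6,
                dimnames = list(c("KRAS", "BRAF"), sprintf("CL%d", 1:6)))
  mat["KRAS", c(1, 2)] <- 1L
  mat["BRAF", c(3, 4)] <- 1L
  ic50 <- c(CL1 = 1, CL2 = 2, CL3 = 3, CL4 = 4, CL5 = 10, CL6 = 20)
  gs <- geneset_association(mat, ic50, genes = c("KRAS", "BRAF"))
  expect_equal(gs$n_mutant, 4L)  # union of disjoint mutant lines
  single <- wilcoxon_association(mat, ic50)
  expect_equal(
    geneset_association(mat, ic50, genes = "KRAS")$p_value,
    single$p_value[single$gene == "KRAS"]
  )

  expect_warning(
    geneset_association(mat, ic50, genes = c("KRAS", "NRAS")),
    "absent from matrix")
  expect_error(
    suppressWarnings(geneset_association(mat, ic50, genes = "HRAS")),
    "no gene-set member")

  # A planted sensitizing shift spread across members: stronger shifts give
  # smaller combined p.
  ps <- sapply(c(1, 0.3, 0.05), function(shift) {
    coh <- simulate_mutation_cohort(
      n_lines = 53, n_genes = 5, effect_genes = c("KRAS", "BRAF", "NRAS"),
      effect_mut_rate = 0.15, ic50_shift = shift, seed = 10)
    geneset_association(coh$matrix, coh$ic50,
                        genes = c("KRAS", "BRAF", "NRAS"))$p_value
  })
  expect_true(ps[2] < ps[1] && ps[3] < ps[2])
})

test_that("type-I error is controlled under a null cohort", {
  coh <- simulate_mutation_cohort(n_lines = 53, n_genes = 500,
                                  mut_rate = 0.3, seed = 2)
  assoc <- wilcoxon_association(coh$matrix, coh$ic50)
  rate <- mean(assoc$p_value < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})

test_that("MAF reading maps columns and feeds the filter", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "muts.tsv")
  readr::write_tsv(tibble::tibble(
    Hugo_Symbol = c("KRAS", "TP53"),
    Tumor_Sample_Barcode = c("A549", "MCF7"),
    Variant_Classification = c("Missense_Mutation", "Silent"),
    CADD_phred = c(25, 10)
  ), path)
  records <- read_maf(path)
  expect_equal(names(records),
               c("cell_line", "gene", "variant_class", "cadd_phred"))
  kept <- filter_mutations(records)
  expect_equal(kept$gene, "KRAS")
})
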