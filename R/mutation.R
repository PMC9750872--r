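#' Canonical variant classes and the default MAF label mapping
#'
#' Variant-classification vocabularies differ across mutation-annotation
#' (MAF) sources; filtering works on a small canonical vocabulary:
#' `snv_missense`, `snv_nonsense`, `snv_nonstop`, `snv_splice`,
#' `snv_start_lost`, `silent`, `noncoding`, `frameshift_indel`,
#' `inframe_insertion`, `inframe_deletion`. Classes starting with `snv_` are
#' single-nucleotide variants and are gated on their CADD Phred score.
#'
#' @return A tibble with columns `raw` (source label) and `class` (canonical
#'   label). Canonical labels map to themselves, so pre-canonicalized tables
#'   pass through.
#' @export
default_variant_class_map <- function() {
  map <- c(
    Missense_Mutation = "snv_missense",
    Nonsense_Mutation = "snv_nonsense",
    Nonstop_Mutation = "snv_nonstop",
    Splice_Site = "snv_splice",
    Translation_Start_Site = "snv_start_lost",
    Start_Codon_SNP = "snv_start_lost",
    Silent = "silent",
    `3'UTR` = "noncoding", `5'UTR` = "noncoding",
    `3'Flank` = "noncoding", `5'Flank` = "noncoding",
    Intron = "noncoding", IGR = "noncoding", RNA = "noncoding",
    lincRNA = "noncoding",
    Frame_Shift_Del = "frameshift_indel",
    Frame_Shift_Ins = "frameshift_indel",
    In_Frame_Del = "inframe_deletion",
    In_Frame_Ins = "inframe_insertion"
  )
  canon <- c("snv_missense", "snv_nonsense", "snv_nonstop", "snv_splice",
             "snv_start_lost", "silent", "noncoding", "frameshift_indel",
             "inframe_insertion", "inframe_deletion")
  tibble::tibble(raw = c(names(map), canon),
                 class = c(unname(map), canon))
}

#' Read a MAF-like mutation table
#'
#' @param path TSV/CSV path.
#' @param column_map Named list mapping the required fields (`gene`,
#'   `cell_line`, `variant_class`, `cadd_phred`) to the file's column names;
#'   defaults cover the common MAF header set.
#' @return Tibble with columns `cell_line`, `gene`, `variant_class`,
#'   `cadd_phred`.
#' @export
read_maf <- function(path,
                     column_map = list(gene = "Hugo_Symbol",
                                       cell_line = "Tumor_Sample_Barcode",
                                       variant_class = "Variant_Classification",
                                       cadd_phred = "CADD_phred")) {
  reader <- if (grepl("\\.csv(\\.gz)?$", path)) readr::read_csv else
    readr::read_tsv
  x <- reader(path, show_col_types = FALSE, progress = FALSE)
  need <- unlist(column_map)
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("mutation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    cell_line = as.character(x[[column_map$cell_line]]),
    gene = as.character(x[[column_map$gene]]),
    variant_class = as.character(x[[column_map$variant_class]]),
    cadd_phred = as.numeric(x[[column_map$cadd_phred]])
  )
}

#' Filter mutation records to predicted-functional variants
#'
#' Drops non-coding variants, silent mutations and in-frame insertions;
#' retains all other indels (frameshifts and in-frame deletions, which can
#' remove essential binding sites); and retains SNVs only when their CADD
#' Phred score is at least `cadd_min` (default 15). SNVs lacking a CADD
#' score are dropped with a warning.
#'
#' @param records Tibble with `cell_line`, `gene`, `variant_class`,
#'   `cadd_phred` (e.g. from [read_maf()]).
#' @param cadd_min CADD Phred retention threshold for SNVs.
#' @param class_map Label mapping table, see [default_variant_class_map()].
#' @param strict Unknown variant classes are an error (`TRUE`) or dropped
#'   with a warning (`FALSE`, default).
#' @return The retained records, with `variant_class` canonicalized.
#' @export
filter_mutations <- function(records, cadd_min = 15,
                             class_map = default_variant_class_map(),
                             strict = FALSE) {
  records <- tibble::as_tibble(records)
  req <- c("cell_line", "gene", "variant_class", "cadd_phred")
  stopifnot(all(req %in% names(records)))
  if (nrow(records) == 0) return(records)

  cls <- class_map$class[match(records$variant_class, class_map$raw)]
  unknown <- unique(records$variant_class[is.na(cls)])
  if (length(unknown) > 0) {
    msg <- paste0("unknown variant class(es): ",
                  paste(unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
  }
  records$variant_class <- cls
  records <- records[!is.na(cls), ]

  is_snv <- startsWith(records$variant_class, "snv_")
  no_cadd <- is_snv & is.na(records$cadd_phred)
  if (any(no_cadd)) {
    warning(sum(no_cadd), " SNV record(s) without a CADD Phred score dropped",
            call. = FALSE)
  }
  keep <- dplyr::case_when(
    records$variant_class %in% c("noncoding", "silent",
                                 "inframe_insertion") ~ FALSE,
    is_snv & is.na(records$cadd_phred) ~ FALSE,
    is_snv ~ records$cadd_phred >= cadd_min,
    TRUE ~ TRUE   # frameshift indels and in-frame deletions
  )
  records[keep, ]
}

#' Build a binary gene-by-cell-line mutation matrix
#'
#' An entry is 1 when the gene has at least one retained mutation in that
#' cell line; multiple mutations of a gene in the same line count once by
#' construction.
#'
#' @param records Retained records from [filter_mutations()].
#' @param cell_lines The cell-line universe (columns of the matrix); lines
#'   with no retained records appear as all-zero columns.
#' @param unknown_line What to do with records naming a cell line outside the
#'   universe: `"error"` (default) or `"drop"` (with a warning).
#' @return Integer 0/1 matrix, genes x cell lines.
#' @export
build_matrix <- function(records, cell_lines,
                         unknown_line = c("error", "drop")) {
  unknown_line <- match.arg(unknown_line)
  stopifnot(length(cell_lines) > 0, !anyDuplicated(cell_lines))
  records <- tibble::as_tibble(records)
  outside <- setdiff(unique(records$cell_line), cell_lines)
  if (length(outside) > 0) {
    msg <- paste0("record(s) name cell line(s) outside the universe: ",
                  paste(outside, collapse = ", "))
    if (unknown_line == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    records <- records[records$cell_line %in% cell_lines, ]
  }
  genes <- sort(unique(records$gene))
  mat <- matrix(0L, nrow = length(genes), ncol = length(cell_lines),
                dimnames = list(genes, cell_lines))
  if (nrow(records) > 0) {
    mat[cbind(match(records$gene, genes),
              match(records$cell_line, cell_lines))] <- 1L
  }
  mat
}

#' Per-gene Wilcoxon rank-sum association between mutation status and IC50
#'
#' For every gene, cell lines are split into mutant (matrix entry 1) and
#' wild-type groups and the IC50 values of the two groups are compared with
#' a two-sided Wilcoxon rank-sum test (exact for small tie-free groups,
#' tie-corrected normal approximation otherwise). Genes with fewer than
#' `min_group` lines in either group get a missing p-value.
#'
#' @param matrix Binary matrix from [build_matrix()].
#' @param ic50 Named numeric vector of IC50s covering every cell line in
#'   `matrix` (any monotone transform gives identical p-values).
#' @param min_group Minimum lines per group for a testable gene (default 2).
#' @return Tibble sorted by p: `gene`, `p_value`, `n_mutant`, `n_wildtype`,
#'   `median_mutant`, `median_wildtype`.
#' @export
wilcoxon_association <- function(matrix, ic50, min_group = 2) {
  lines <- colnames(matrix)
  if (!all(lines %in% names(ic50))) {
    stop("IC50 missing for cell line(s): ",
         paste(setdiff(lines, names(ic50)), collapse = ", "), call. = FALSE)
  }
  vals <- ic50[lines]
  if (any(is.na(vals))) stop("IC50 contains missing values", call. = FALSE)

  res <- lapply(rownames(matrix), function(g) {
    mut <- matrix[g, ] == 1L
    n_mut <- sum(mut); n_wt <- sum(!mut)
    p <- if (n_mut >= min_group && n_wt >= min_group) {
      mann_whitney_p(vals[mut], vals[!mut])
    } else NA_real_
    tibble::tibble(
      gene = g, p_value = p, n_mutant = n_mut, n_wildtype = n_wt,
      median_mutant = if (n_mut > 0) stats::median(vals[mut]) else NA_real_,
      median_wildtype = if (n_wt > 0) stats::median(vals[!mut]) else NA_real_
    )
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$p_value)
}

#' Gene-set association between combined mutation status and IC50
#'
#' A cell line is "mutant" when at least one member gene of the set carries a
#' retained mutation; the combined status is then tested exactly like a
#' single gene. The default set is the Ras/Raf pathway set
#' KRAS, NRAS, HRAS, NF1, BRAF.
#'
#' @inheritParams wilcoxon_association
#' @param genes Member genes; members absent from the matrix are dropped
#'   with a warning, an empty effective set is an error.
#' @param label Row label for the result.
#' @return One-row tibble in the [wilcoxon_association()] format.
#' @export
geneset_association <- function(matrix, ic50,
                                genes = c("KRAS", "NRAS", "HRAS", "NF1",
                                          "BRAF"),
                                label = paste(genes, collapse = "+"),
                                min_group = 2) {
  present <- intersect(genes, rownames(matrix))
  absent <- setdiff(genes, rownames(matrix))
  if (length(absent) > 0) {
    warning("gene-set member(s) absent from matrix: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0) {
    stop("no gene-set member present in the mutation matrix", call. = FALSE)
  }
  combined <- matrix(as.integer(
    colSums(matrix[present, , drop = FALSE]) > 0
  ), nrow = 1, dimnames = list(label, colnames(matrix)))
  wilcoxon_association(combined, ic50, min_group = min_group)
}

#' Simulate a synthetic mutation/IC50 cohort
#'
#' Generates a purely synthetic cell-line panel: Bernoulli mutation calls per
#' gene and log-normal IC50s, with an optional planted multiplicative IC50
#' shift for lines mutated in a chosen gene set (shift < 1 means mutants are
#' more sensitive). Used for null-calibration and power checks of the
#' association stage.
#'
#' @param n_lines Number of cell lines (default 53).
#' @param n_genes Number of background genes.
#' @param mut_rate Per-gene per-line mutation probability.
#' @param effect_genes Character vector of planted-effect gene names
#'   (appended to the background genes).
#' @param effect_mut_rate Mutation probability for the planted genes.
#' @param ic50_shift Multiplicative IC50 factor for lines mutant in any
#'   planted gene (1 = null).
#' @param ic50_meanlog,ic50_sdlog Log-normal IC50 parameters (molar scale).
#' @param seed Integer seed.
#' @return List with `matrix` (binary gene x line) and `ic50` (named vector).
#' @export
simulate_mutation_cohort <- function(n_lines = 53, n_genes = 100,
                                     mut_rate = 0.3,
                                     effect_genes = character(0),
                                     effect_mut_rate = 0.3,
                                     ic50_shift = 1,
                                     ic50_meanlog = log(3e-7),
                                     ic50_sdlog = 1,
                                     seed = 1L) {
  set.seed(derive_seed(seed, 5))
  lines <- sprintf("CL%03d", seq_len(n_lines))
  genes <- sprintf("BG%04d", seq_len(n_genes))
  mat <- matrix(stats::rbinom(n_genes * n_lines, 1, mut_rate),
                nrow = n_genes, dimnames = list(genes, lines))
  if (length(effect_genes) > 0) {
    eff <- matrix(stats::rbinom(length(effect_genes) * n_lines, 1,
                                effect_mut_rate),
                  nrow = length(effect_genes),
                  dimnames = list(effect_genes, lines))
    mat <- rbind(mat, eff)
  }
  ic50 <- stats::rlnorm(n_lines, ic50_meanlog, ic50_sdlog)
  if (length(effect_genes) > 0 && ic50_shift != 1) {
    carrier <- colSums(mat[effect_genes, , drop = FALSE]) > 0
    ic50[carrier] <- ic50[carrier] * ic50_shift
  }
  names(ic50) <- lines
  storage.mode(mat) <- "integer"
  list(matrix = mat, ic50 = ic50)
}
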