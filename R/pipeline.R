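#' Run the full screen-scoring pipeline
#'
#' Orchestrates counting (or count loading, or simulation), phenotype
#' computation, negative-control pseudo-gene construction, gene scoring, TSS
#' collapse and hit calling, and writes every table plus a provenance record.
#'
#' Inputs are given as a config list with the blocks:
#' * exactly one of `sim` (a [sim_config()]), `counts` (a [count_table()] or
#'   a counts TSV path) or `fastq` (a samples tibble for [count_reads()]);
#' * `library`: a library tibble or CSV/FASTA path (not needed with `sim`);
#' * `phenotype`: a [phenotype_params()] (default
#'   `phenotype_params(doublings_untreated = 10)`);
#' * `scoring`: list with `phenotype_col` (default `"rho"`), `threshold`
#'   (default 7), `k` (default 3), `n_pseudo`, `size`, `seed` (default 1);
#' * `count`: list with `offset`, `scan` for the FASTQ path.
#'
#' @param config Config list as above.
#' @param outdir Output directory; receives `phenotypes.tsv`,
#'   `gene_scores_per_tss.tsv`, `gene_scores.tsv`, `hits.tsv`, `volcano.tsv`
#'   (+ `volcano.png` if `figures = TRUE`) and `provenance.json`.
#' @param figures Also render the volcano figure (default `FALSE`).
#' @return Invisibly, a list with `library`, `counts`, `phenotypes`,
#'   `scores_per_tss`, `scores`, `hits`, `truth` (simulation only).
#' @export
run_screen_pipeline <- function(config, outdir, figures = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  if (!is.null(config$sim)) {
    library <- simulate_library(config$sim)
    sim <- simulate_screen(library, config$sim)
    counts <- sim$counts
    truth <- sim$truth
  } else {
    library <- config$library
    if (is.character(library)) library <- load_library(library)
    validate_library(library)
    if (!is.null(config$counts)) {
      counts <- config$counts
      if (is.character(counts)) counts <- read_counts(counts, library)
    } else if (!is.null(config$fastq)) {
      cc <- config$count %||% list()
      counts <- count_reads(config$fastq, library,
                            offset = cc$offset %||% 0,
                            scan = cc$scan %||% FALSE)
    } else {
      stop("config needs one of `sim`, `counts` or `fastq`", call. = FALSE)
    }
  }

  params <- config$phenotype %||%
    phenotype_params(doublings_untreated = 10)
  phen <- compute_phenotypes(counts, library, params)

  sc <- config$scoring %||% list()
  ncg <- make_negative_control_genes(library,
                                     n_pseudo = sc$n_pseudo,
                                     size = sc$size,
                                     seed = sc$seed %||% 1L)
  per_tss <- score_genes(phen, ncg,
                         phenotype_col = sc$phenotype_col %||% "rho",
                         threshold = sc$threshold %||% 7,
                         k = sc$k %||% 3)
  scores <- collapse_tss(per_tss)
  hits <- scores[scores$is_hit & !scores$is_negative_control, ]

  readr::write_tsv(phen, file.path(outdir, "phenotypes.tsv"))
  readr::write_tsv(per_tss, file.path(outdir, "gene_scores_per_tss.tsv"))
  readr::write_tsv(scores, file.path(outdir, "gene_scores.tsv"))
  readr::write_tsv(hits, file.path(outdir, "hits.tsv"))
  export_volcano(scores, file.path(outdir, "volcano.tsv"),
                 fig_path = if (figures) file.path(outdir, "volcano.png"))
  write_provenance(config, outdir, stage = "screen",
                   notes = list(
                     n_sgrnas = nrow(library),
                     n_hits = nrow(hits),
                     ncg_mu = attr(per_tss, "ncg_mu"),
                     ncg_sigma = attr(per_tss, "ncg_sigma")
                   ))

  invisible(list(library = library, counts = counts, phenotypes = phen,
                 scores_per_tss = per_tss, scores = scores, hits = hits,
                 truth = truth))
}

#' Run the mutation-vs-IC50 association pipeline
#'
#' Filters a MAF-like variant table, builds the binary mutation matrix over
#' the IC50'd cell-line universe, runs per-gene and gene-set Wilcoxon
#' rank-sum association, and writes the sorted reports.
#'
#' @param config List with blocks: `maf` (records tibble or path for
#'   [read_maf()]), `ic50` (named vector, or tibble with `cell_line`, `ic50`),
#'   `cadd_min` (default 15), `gene_set` (default KRAS/NRAS/HRAS/NF1/BRAF;
#'   `NULL` to skip), `min_group` (default 2), `strict` (default FALSE).
#' @param outdir Output directory; receives `mutation_matrix.tsv`,
#'   `association.tsv`, `geneset_association.tsv`, `provenance.json`.
#' @return Invisibly, list with `matrix`, `association`, `geneset`.
#' @export
run_assoc_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  records <- config$maf
  if (is.character(records)) records <- read_maf(records)

  ic50 <- config$ic50
  if (is.data.frame(ic50)) {
    ic50 <- stats::setNames(ic50$ic50, ic50$cell_line)
  }
  if (is.null(names(ic50))) stop("`ic50` must be named by cell line",
                                 call. = FALSE)

  retained <- filter_mutations(records,
                               cadd_min = config$cadd_min %||% 15,
                               strict = config$strict %||% FALSE)
  mat <- build_matrix(retained, cell_lines = names(ic50),
                      unknown_line = config$unknown_line %||% "error")

  if (nrow(mat) == 0) {
    warning("no retained mutations; association report is empty",
            call. = FALSE)
    assoc <- tibble::tibble(gene = character(0), p_value = numeric(0),
                            n_mutant = integer(0), n_wildtype = integer(0),
                            median_mutant = numeric(0),
                            median_wildtype = numeric(0))
    gs <- NULL
  } else {
    assoc <- wilcoxon_association(mat, ic50,
                                  min_group = config$min_group %||% 2)
    gene_set <- if ("gene_set" %in% names(config)) config$gene_set else
      c("KRAS", "NRAS", "HRAS", "NF1", "BRAF")
    gs <- if (is.null(gene_set)) NULL else
      tryCatch(geneset_association(mat, ic50, genes = gene_set,
                                   min_group = config$min_group %||% 2),
               error = function(e) {
                 warning("gene-set association skipped: ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
  }

  mat_df <- tibble::as_tibble(mat, rownames = "gene")
  readr::write_tsv(mat_df, file.path(outdir, "mutation_matrix.tsv"))
  readr::write_tsv(assoc, file.path(outdir, "association.tsv"))
  if (!is.null(gs)) {
    readr::write_tsv(gs, file.path(outdir, "geneset_association.tsv"))
  }
  write_provenance(config, outdir, stage = "assoc",
                   notes = list(n_records = nrow(tibble::as_tibble(records)),
                                n_retained = nrow(retained),
                                n_genes_tested = sum(!is.na(assoc$p_value))))
  invisible(list(matrix = mat, association = assoc, geneset = gs))
}

# Provenance: resolved config hash, package version, session info.
# No timestamps, so identical runs produce identical records.
write_provenance <- function(config, outdir, stage, notes = list()) {
  serializable <- serialize_config(config)
  rec <- list(
    stage = stage,
    package = "chemgenscreen",
    version = as.character(utils::packageVersion("chemgenscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = serializable,
    config_hash = rlang::hash(serializable),
    notes = notes
  )
  jsonlite::write_json(rec, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(rec)
}

# Strip non-serializable payloads (tibbles, count tables) down to summaries
# so the provenance record stays small and stable.
serialize_config <- function(x) {
  if (inherits(x, "count_table")) {
    return(list(count_table = list(n_sgrnas = nrow(x$counts),
                                   samples = as.list(x$samples$name))))
  }
  if (is.data.frame(x)) {
    return(list(data_frame = list(nrow = nrow(x),
                                  columns = as.list(names(x)))))
  }
  if (is.list(x)) return(lapply(x, serialize_config))
  x
}
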