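#' Reserved gene/TSS label for non-targeting control sgRNAs
#'
#' @return The sentinel string used in the `gene` and `tss` fields of
#'   non-targeting library records.
#' @export
nontargeting_label <- function() "non-targeting"

#' Simulate an sgRNA library reference
#'
#' Generates a library table with `n_genes * n_tss_per_gene` targeted groups
#' of `sgrnas_per_gene` members each, plus `n_nontargeting` non-targeting
#' controls. Protospacer sequences are unique fixed-length nucleotide strings.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `sgrna_id`, `sequence`, `gene`, `tss`,
#'   `is_nontargeting` (see [load_library()] for the invariants).
#' @examples
#' lib <- simulate_library(sim_config(n_genes = 2, n_nontargeting = 10))
#' nrow(lib)   # 2 * 5 + 10
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_targeted <- config$n_genes * config$n_tss_per_gene * config$sgrnas_per_gene
  n_total <- n_targeted + config$n_nontargeting
  L <- config$protospacer_length
  if (4^L < 4 * n_total) {
    stop("protospacer length ", L, " cannot host ", n_total,
         " unique sequences; increase `protospacer_length`", call. = FALSE)
  }

  genes <- sprintf("G%05d", seq_len(config$n_genes))
  tss_labels <- sprintf("P%d", seq_len(config$n_tss_per_gene))
  grid <- expand.grid(sg = seq_len(config$sgrnas_per_gene),
                      tss = tss_labels, gene = genes,
                      stringsAsFactors = FALSE)
  targeted <- tibble::tibble(
    sgrna_id = sprintf("%s_%s_sg%d", grid$gene, grid$tss, grid$sg),
    gene = grid$gene,
    tss = grid$tss,
    is_nontargeting = FALSE
  )
  ntc <- tibble::tibble(
    sgrna_id = sprintf("NTC_sg%05d", seq_len(config$n_nontargeting)),
    gene = nontargeting_label(),
    tss = nontargeting_label(),
    is_nontargeting = TRUE
  )
  lib <- dplyr::bind_rows(targeted, ntc)

  # Sequences are drawn in sorted-id order so the draw is invariant to how
  # the records above happen to be stacked.
  ord <- order(lib$sgrna_id)
  set.seed(derive_seed(config$seed, 0))
  seqs <- random_protospacers(n_total, L)
  lib$sequence <- NA_character_
  lib$sequence[ord] <- seqs
  lib[, c("sgrna_id", "sequence", "gene", "tss", "is_nontargeting")]
}

random_protospacers <- function(n, width, max_tries = 100L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("failed to draw ", n, " unique protospacers of length ", width,
           call. = FALSE)
    }
    need <- n - length(out)
    draw <- matrix(sample(c("A", "C", "G", "T"), need * width, replace = TRUE),
                   nrow = need)
    out <- unique(c(out, apply(draw, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}

#' Simulate a pooled chemical-genetic screen from a library
#'
#' Draws true per-gene gamma/rho phenotypes and per-sgRNA activities, runs the
#' exponential growth/selection model over the configured population
#' doublings, and samples sequencing counts for three samples (t0, untreated,
#' treated).
#'
#' The abundance model is defined directly on the two contrasts the scoring
#' pipeline uses: expected log2 enrichment of sgRNA i (gene g, activity a_i)
#' is `D_u * a_i * gamma_g` for untreated vs t0 and
#' `delta_D * a_i * rho_g` for treated vs untreated, on top of a log-normal
#' t0 representation skew. Counts are multinomial at the configured total
#' depth, or Dirichlet-multinomial when `dispersion > 0`.
#'
#' @param library A library tibble from [simulate_library()] (row order is
#'   irrelevant; all draws are keyed to sorted ids).
#' @param config The [sim_config()] used to build the library.
#' @return A list with elements:
#'   * `counts`: a [count_table()] with samples `t0`, `untreated`, `treated`.
#'   * `truth`: list of `gene_truth` (gene, tss, true_gamma, true_rho, label)
#'     and `sgrna_truth` (sgrna_id, gene, tss, activity, true_gamma,
#'     true_rho). Non-targeting sgRNAs have both phenotypes exactly 0.
#' @export
simulate_screen <- function(library, config) {
  stopifnot(inherits(config, "sim_config"))
  validate_library(library)
  lib <- library[order(library$sgrna_id), ]
  n_sgrna <- nrow(lib)

  genes <- sort(unique(lib$gene[!lib$is_nontargeting]))
  n_genes <- length(genes)

  set.seed(derive_seed(config$seed, 1))
  n_rho <- round(config$frac_rho_hits * n_genes)
  n_gam <- round(config$frac_gamma_hits * n_genes)
  rho_hits <- sample(genes, n_rho)
  gam_hits <- sample(genes, n_gam)
  true_rho <- stats::setNames(rep(0, n_genes), genes)
  true_gamma <- stats::setNames(rep(0, n_genes), genes)
  true_rho[rho_hits] <- draw_dist(n_rho, config$rho_effect_dist)
  true_gamma[gam_hits] <- draw_dist(n_gam, config$gamma_effect_dist)

  activity <- rep(0, n_sgrna)
  targeted <- !lib$is_nontargeting
  activity[targeted] <- draw_dist(sum(targeted), config$activity_dist)
  activity <- pmin(pmax(activity, 0), 1)

  gamma_i <- ifelse(targeted, true_gamma[lib$gene], 0)
  rho_i <- ifelse(targeted, true_rho[lib$gene], 0)

  # Expected frequencies in each arm.
  f0 <- stats::rlnorm(n_sgrna, meanlog = 0, sdlog = config$t0_sigma)
  f0 <- f0 / sum(f0)
  f_unt <- f0 * 2^(config$doublings_untreated * activity * gamma_i)
  f_unt <- f_unt / sum(f_unt)
  f_tr <- f_unt * 2^(config$doubling_difference * activity * rho_i)
  f_tr <- f_tr / sum(f_tr)

  depth <- round(config$mean_reads_per_sgrna * n_sgrna)
  set.seed(derive_seed(config$seed, 2))
  counts <- cbind(
    t0        = draw_counts(f0, depth, config$dispersion),
    untreated = draw_counts(f_unt, depth, config$dispersion),
    treated   = draw_counts(f_tr, depth, config$dispersion)
  )
  rownames(counts) <- lib$sgrna_id

  samples <- tibble::tibble(
    name = c("t0", "untreated", "treated"),
    role = c("t0", "untreated", "treated"),
    doublings = c(0, config$doublings_untreated,
                  config$doublings_untreated - config$doubling_difference)
  )
  ct <- count_table(counts, samples)
  attr(ct, "doubling_difference") <- config$doubling_difference

  label <- rep("none", n_genes)
  names(label) <- genes
  label[gam_hits] <- "gamma-hit"
  label[true_rho < 0] <- "rho-sensitizing"
  label[true_rho > 0] <- "rho-protective"

  gene_truth <- tidyr::expand_grid(
    gene = genes,
    tss = sprintf("P%d", seq_len(config$n_tss_per_gene))
  )
  gene_truth$true_gamma <- true_gamma[gene_truth$gene]
  gene_truth$true_rho <- true_rho[gene_truth$gene]
  gene_truth$label <- label[gene_truth$gene]

  sgrna_truth <- tibble::tibble(
    sgrna_id = lib$sgrna_id,
    gene = lib$gene,
    tss = lib$tss,
    activity = activity,
    true_gamma = gamma_i,
    true_rho = rho_i
  )

  list(counts = ct, truth = list(gene_truth = gene_truth,
                                 sgrna_truth = sgrna_truth))
}

# Multinomial or Dirichlet-multinomial counts at fixed total depth.
# `dispersion` is scaled so that, for a typical sgRNA, it approximates the
# excess squared CV of its sampled frequency.
draw_counts <- function(freq, depth, dispersion) {
  if (dispersion > 0) {
    alpha <- freq * length(freq) / dispersion
    g <- stats::rgamma(length(freq), shape = alpha, rate = 1)
    # Guard against all-zero gamma draws at extreme dispersion.
    if (sum(g) == 0) g <- freq
    freq <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = freq)[, 1])
}

#' Emit simulated FASTQ reads for a count table
#'
#' Writes one FASTQ file per sample; each sgRNA contributes exactly its count
#' of reads. Reads consist of a constant scaffold with the protospacer placed
#' at `offset` (0-based), optionally corrupted by a uniform per-base
#' substitution error. Qualities are a uniform placeholder.
#'
#' @param counts A [count_table()].
#' @param library The matching library tibble.
#' @param dir Output directory (created if missing).
#' @param offset 0-based position of the protospacer within each read.
#' @param read_length Total read length; default `offset + protospacer length`.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param gzip Write `.fastq.gz` instead of `.fastq`.
#' @param seed Seed for the error process (ignored when `error_rate = 0`).
#' @return A tibble with columns `name`, `role`, `doublings`, `path`, suitable
#'   for [count_reads()].
#' @export
emit_fastq <- function(counts, library, dir, offset = 0, read_length = NULL,
                       error_rate = 0, gzip = FALSE, seed = 1L) {
  stopifnot(inherits(counts, "count_table"))
  validate_library(library)
  if (error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  }
  L <- nchar(library$sequence[1])
  if (is.null(read_length)) read_length <- offset + L
  if (read_length < offset + L) {
    stop("`read_length` (", read_length, ") shorter than offset + ",
         "protospacer length (", offset + L, ")", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  scaffold <- paste(rep(c("G", "T", "C", "A"),
                        length.out = read_length), collapse = "")
  prefix <- substr(scaffold, 1, offset)
  suffix_len <- read_length - offset - L
  suffix <- if (suffix_len > 0) {
    substr(scaffold, offset + L + 1, read_length)
  } else ""

  seqs <- stats::setNames(library$sequence, library$sgrna_id)
  qual <- strrep("I", read_length)
  set.seed(derive_seed(seed, 3))

  out <- counts$samples
  out$path <- NA_character_
  for (s in seq_len(nrow(out))) {
    nm <- out$name[s]
    cvec <- counts$counts[, nm]
    reads <- rep(paste0(prefix, seqs[rownames(counts$counts)], suffix), cvec)
    if (error_rate > 0 && length(reads) > 0) {
      reads <- corrupt_reads(reads, error_rate)
    }
    path <- file.path(dir, paste0(nm, if (gzip) ".fastq.gz" else ".fastq"))
    con <- if (gzip) gzfile(path, "w") else file(path, "w")
    if (length(reads) > 0) {
      ids <- sprintf("@%s.read%d", nm, seq_along(reads))
      writeLines(paste(ids, reads, "+", qual, sep = "\n"), con, sep = "\n")
    }
    close(con)
    out$path[s] <- path
  }
  out
}

# Uniform per-base substitutions; each error replaces a base with one of the
# three other bases.
corrupt_reads <- function(reads, rate) {
  width <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), size = width, prob = rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(width, n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write simulation ground truth to TSV
#'
#' @param truth The `truth` element returned by [simulate_screen()].
#' @param gene_path,sgrna_path Output TSV paths for the gene-level and
#'   sgRNA-level truth tables.
#' @return Invisibly, the two paths.
#' @export
write_truth <- function(truth, gene_path, sgrna_path) {
  readr::write_tsv(truth$gene_truth, gene_path)
  readr::write_tsv(truth$sgrna_truth, sgrna_path)
  invisible(c(gene_path, sgrna_path))
}
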