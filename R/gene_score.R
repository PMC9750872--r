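#' Collapse sgRNA phenotypes to a single gene-level phenotype
#'
#' The gene phenotype is the mean of the `k` sgRNA phenotypes of largest
#' absolute value (signed values are averaged). With fewer than `k` values
#' available, all are averaged. Ties in absolute value are broken by
#' lexicographic `sgrna_id` order for determinism.
#'
#' @param values Per-sgRNA phenotype values for one gene/TSS group.
#' @param ids Optional sgRNA ids aligned to `values` (for tie-breaking).
#' @param k Number of top sgRNAs to average (default 3).
#' @return The collapsed phenotype (scalar).
#' @examples
#' collapse_gene(c(-0.50, 0.40, -0.45, 0.01, -0.02))  # mean of top 3 by |.|
#' @export
collapse_gene <- function(values, ids = NULL, k = 3) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  if (is.null(ids)) ids <- sprintf("sg%06d", seq_along(values))
  ord <- order(-abs(values), ids)
  mean(values[ord][seq_len(min(k, length(values)))])
}

#' Two-sided Mann-Whitney U p-value
#'
#' Compares one gene's sgRNA phenotypes with the non-targeting control
#' phenotypes. The p-value is exact (by enumeration of the U null
#' distribution) when both groups have at most `exact_max` observations and
#' the pooled data are tie-free; otherwise the tie-corrected normal
#' approximation with continuity correction is used. The result is clamped
#' to (0, 1].
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max Largest group size for which the exact null is used.
#' @return The two-sided p-value.
#' @export
mann_whitney_p <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  tie_free <- !anyDuplicated(c(x, y))
  exact <- tie_free && length(x) <= exact_max && length(y) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
  # Fully tied data degenerate the normal approximation (zero variance);
  # such data carry no evidence against the null.
  if (!is.finite(p)) p <- 1
  min(max(p, .Machine$double.xmin), 1)
}

#' Build negative-control pseudo-genes from non-targeting sgRNAs
#'
#' Each pseudo-gene is a random group of non-targeting sgRNA ids of the given
#' size, sampled without replacement within a group and independently across
#' groups. Groups duplicating an exact member set are resampled. Scoring
#' pseudo-genes with the same machinery as real genes calibrates the
#' phenotype z-score and the empirical false-positive rate.
#'
#' @param library The library tibble.
#' @param n_pseudo Number of pseudo-genes; default = number of real gene/TSS
#'   groups in the library.
#' @param size Members per pseudo-gene; default = the modal number of sgRNAs
#'   per gene/TSS group.
#' @param seed Integer seed (sampling is deterministic given it).
#' @return A tibble with columns `gene` (pseudo-gene label), `sgrna_id`;
#'   attributes `seed` and `size`.
#' @export
make_negative_control_genes <- function(library, n_pseudo = NULL, size = NULL,
                                        seed = 1L) {
  validate_library(library)
  nt_ids <- sort(library$sgrna_id[library$is_nontargeting])
  groups <- unique(paste(library$gene[!library$is_nontargeting],
                         library$tss[!library$is_nontargeting]))
  if (is.null(n_pseudo)) n_pseudo <- length(groups)
  if (is.null(size)) {
    per_group <- table(paste(library$gene[!library$is_nontargeting],
                             library$tss[!library$is_nontargeting]))
    size <- as.integer(names(sort(table(as.integer(per_group)),
                                  decreasing = TRUE))[1])
  }
  if (size > length(nt_ids)) {
    stop("pseudo-gene size ", size, " exceeds the ", length(nt_ids),
         " available non-targeting sgRNAs", call. = FALSE)
  }
  set.seed(derive_seed(seed, 4))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  members <- vector("list", n_pseudo)
  for (i in seq_len(n_pseudo)) {
    repeat {
      draw <- sort(sample(nt_ids, size))
      key <- paste(draw, collapse = ";")
      if (is.null(seen[[key]])) break
    }
    seen[[key]] <- TRUE
    members[[i]] <- draw
  }
  out <- tibble::tibble(
    gene = rep(sprintf("pseudo_%05d", seq_len(n_pseudo)), each = size),
    sgrna_id = unlist(members)
  )
  attr(out, "seed") <- seed
  attr(out, "size") <- size
  out
}

#' Score genes from sgRNA phenotypes and call hits by discriminant score
#'
#' For every gene/TSS group the phenotype is collapsed with [collapse_gene()]
#' (top-`k` by absolute value) and a two-sided Mann-Whitney p-value is
#' computed from all of the group's sgRNA phenotypes against the full set of
#' non-targeting sgRNA phenotypes. Negative-control pseudo-genes are scored
#' identically; the mean and standard deviation of their collapsed phenotypes
#' define the phenotype z-score `z = (phenotype - mu_NCG) / sigma_NCG`. The
#' hit statistic is the discriminant score `|z| * (-log10 p)`, thresholded at
#' `threshold` (default 7), two-sided so both sensitizing (negative
#' phenotype) and protective (positive) hits are callable.
#'
#' @param phenotypes Tibble from [compute_phenotypes()] (or any tibble with
#'   `sgrna_id`, `gene`, `tss`, `is_nontargeting`, `filtered` and the chosen
#'   phenotype column).
#' @param ncg Pseudo-gene membership from [make_negative_control_genes()].
#' @param phenotype_col Which phenotype to score: `"rho"` (drug sensitivity,
#'   default) or `"gamma"` (growth).
#' @param threshold Discriminant threshold for `is_hit` (default 7).
#' @param k Top-k for the collapse (default 3).
#' @return A tibble with one row per gene/TSS group and per pseudo-gene:
#'   `gene`, `tss`, `phenotype`, `p_value`, `z`, `discriminant`,
#'   `n_sgrnas_used`, `is_hit`, `direction`, `is_negative_control`, `bh_fdr`
#'   (BH-adjusted p over real genes; informational, never gates `is_hit`).
#' @export
score_genes <- function(phenotypes, ncg, phenotype_col = "rho",
                        threshold = 7, k = 3) {
  ph <- tibble::as_tibble(phenotypes)
  stopifnot(phenotype_col %in% names(ph))
  ph$value <- ph[[phenotype_col]]
  usable <- !ph$filtered & !is.na(ph$value)

  nt_values <- ph$value[ph$is_nontargeting & usable]
  if (length(nt_values) == 0) {
    stop("no usable non-targeting sgRNA phenotypes", call. = FALSE)
  }

  score_group <- function(values, ids) {
    values_ok <- values[!is.na(values)]
    if (length(values_ok) == 0) {
      return(list(phenotype = NA_real_, p_value = NA_real_, n = 0L))
    }
    list(phenotype = collapse_gene(values, ids, k = k),
         p_value = mann_whitney_p(values_ok, nt_values),
         n = length(values_ok))
  }

  real <- ph[!ph$is_nontargeting & usable, ]
  real_scores <- real |>
    dplyr::group_by(.data$gene, .data$tss) |>
    dplyr::summarise(res = list(score_group(.data$value, .data$sgrna_id)),
                     .groups = "drop")

  # Genes whose sgRNAs were all filtered still get a (missing) row.
  all_groups <- dplyr::distinct(ph[!ph$is_nontargeting,
                                   c("gene", "tss")])
  dropped <- dplyr::anti_join(all_groups, real_scores[, c("gene", "tss")],
                              by = c("gene", "tss"))
  if (nrow(dropped) > 0) {
    message(nrow(dropped), " gene/TSS group(s) had no unfiltered sgRNAs; ",
            "emitted with missing scores")
    dropped$res <- list(list(phenotype = NA_real_, p_value = NA_real_,
                             n = 0L))
    real_scores <- dplyr::bind_rows(real_scores, dropped)
  }

  nt_tbl <- ph[match(ncg$sgrna_id, ph$sgrna_id), ]
  pseudo_scores <- tibble::tibble(gene = ncg$gene,
                                  sgrna_id = ncg$sgrna_id,
                                  value = nt_tbl$value,
                                  filtered = nt_tbl$filtered) |>
    dplyr::filter(!.data$filtered) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(res = list(score_group(.data$value, .data$sgrna_id)),
                     .groups = "drop")
  pseudo_scores$tss <- nontargeting_label()

  unpack <- function(df, is_ncg) {
    tibble::tibble(
      gene = df$gene,
      tss = df$tss,
      phenotype = vapply(df$res, `[[`, numeric(1), "phenotype"),
      p_value = vapply(df$res, `[[`, numeric(1), "p_value"),
      n_sgrnas_used = vapply(df$res, `[[`, integer(1), "n"),
      is_negative_control = is_ncg
    )
  }
  scores <- dplyr::bind_rows(unpack(real_scores, FALSE),
                             unpack(pseudo_scores, TRUE))

  mu <- mean(scores$phenotype[scores$is_negative_control], na.rm = TRUE)
  sigma <- stats::sd(scores$phenotype[scores$is_negative_control],
                     na.rm = TRUE)
  if (!is.finite(sigma) || sigma == 0) {
    stop("degenerate negative-control genes: zero phenotype spread",
         call. = FALSE)
  }

  scores$z <- (scores$phenotype - mu) / sigma
  scores$discriminant <- abs(scores$z) * (-log10(scores$p_value))
  scores$is_hit <- !is.na(scores$discriminant) &
    scores$discriminant >= threshold
  scores$direction <- dplyr::case_when(
    !scores$is_hit ~ "none",
    scores$phenotype < 0 ~ "sensitizing",
    TRUE ~ "protective"
  )
  scores$bh_fdr <- NA_real_
  realrows <- !scores$is_negative_control
  scores$bh_fdr[realrows] <- stats::p.adjust(scores$p_value[realrows],
                                             method = "BH")
  scores <- dplyr::arrange(scores, .data$is_negative_control, .data$gene,
                           .data$tss)
  attr(scores, "ncg_mu") <- mu
  attr(scores, "ncg_sigma") <- sigma
  attr(scores, "threshold") <- threshold
  attr(scores, "phenotype_col") <- phenotype_col
  scores
}

#' Collapse per-TSS gene scores to one row per gene
#'
#' Genes with several independently scored TSSs keep the row of the TSS with
#' the lowest Mann-Whitney p-value, verbatim. Ties on p are broken by larger
#' absolute phenotype, then by TSS label order. Pseudo-gene rows pass through
#' unchanged.
#'
#' @param scores A [score_genes()] table.
#' @return The collapsed table, one row per gene.
#' @export
collapse_tss <- function(scores) {
  scores <- tibble::as_tibble(scores)
  pick <- function(df) {
    ord <- order(df$p_value, -abs(df$phenotype), df$tss)
    df[ord[1], ]
  }
  real <- scores[!scores$is_negative_control, ]
  collapsed <- real |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(~ pick(.x)) |>
    dplyr::ungroup()
  out <- dplyr::bind_rows(collapsed,
                          scores[scores$is_negative_control, ])
  for (a in c("ncg_mu", "ncg_sigma", "threshold", "phenotype_col")) {
    attr(out, a) <- attr(scores, a)
  }
  out
}

#' Volcano-plot export of a gene score table
#'
#' Writes every (phenotype, -log10 p) pair of the score table as TSV so
#' figures never need to be parsed, and optionally draws the volcano with the
#' discriminant threshold boundary.
#'
#' @param scores A [score_genes()] (or [collapse_tss()]) table.
#' @param tsv_path Output TSV path.
#' @param fig_path Optional figure path (PNG/SVG/PDF, by extension).
#' @return Invisibly, the exported tibble.
#' @export
export_volcano <- function(scores, tsv_path, fig_path = NULL) {
  dat <- tibble::tibble(
    gene = scores$gene,
    tss = scores$tss,
    phenotype = scores$phenotype,
    neg_log10_p = -log10(scores$p_value),
    z = scores$z,
    discriminant = scores$discriminant,
    is_hit = scores$is_hit,
    is_negative_control = scores$is_negative_control
  )
  readr::write_tsv(dat, tsv_path)
  if (!is.null(fig_path)) {
    mu <- attr(scores, "ncg_mu")
    sigma <- attr(scores, "ncg_sigma")
    thr <- attr(scores, "threshold") %||% 7
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$phenotype,
                                           y = .data$neg_log10_p)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$is_hit,
                                       shape = .data$is_negative_control),
                          alpha = 0.6, size = 1) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                              `TRUE` = "firebrick")) +
      ggplot2::labs(x = "gene phenotype", y = "-log10 Mann-Whitney p",
                    colour = "hit", shape = "negative control")
    if (!is.null(mu) && !is.null(sigma)) {
      grid <- seq(min(dat$phenotype, na.rm = TRUE),
                  max(dat$phenotype, na.rm = TRUE), length.out = 400)
      zb <- abs((grid - mu) / sigma)
      boundary <- tibble::tibble(phenotype = grid[zb > 0],
                                 neg_log10_p = thr / zb[zb > 0])
      boundary <- boundary[boundary$neg_log10_p <=
                             max(dat$neg_log10_p, na.rm = TRUE) * 1.1, ]
      p <- p + ggplot2::geom_line(data = boundary, linetype = "dashed",
                                  colour = "grey20")
    }
    ggplot2::ggsave(fig_path, p, width = 6, height = 5)
  }
  invisible(dat)
}
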