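#' Construct an sgRNA count table
#'
#' A light container for the sgRNA x sample matrix of non-negative integer
#' counts, per-sample metadata (role in the screen, doublings from t0), and
#' the per-sample unmapped-read tally.
#'
#' @param counts Integer matrix, rows named by `sgrna_id`, columns named by
#'   sample name.
#' @param samples Tibble with columns `name`, `role` (one of `t0`,
#'   `untreated`, `treated`) and optionally `doublings` (from t0).
#' @param unmapped Named numeric vector of unmapped reads per sample
#'   (default 0).
#' @return An object of class `"count_table"`: a list with elements `counts`,
#'   `samples`, `unmapped`.
#' @export
count_table <- function(counts, samples, unmapped = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sgrna_id rownames and sample colnames",
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  samples <- tibble::as_tibble(samples)
  if (!all(c("name", "role") %in% names(samples))) {
    stop("`samples` needs columns `name` and `role`", call. = FALSE)
  }
  bad_role <- setdiff(samples$role, c("t0", "untreated", "treated"))
  if (length(bad_role) > 0) {
    stop("unknown sample role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(samples$name, colnames(counts)) ||
      anyDuplicated(samples$name)) {
    stop("sample metadata names must match count columns exactly",
         call. = FALSE)
  }
  if (!("doublings" %in% names(samples))) samples$doublings <- NA_real_
  if (is.null(unmapped)) {
    unmapped <- stats::setNames(rep(0, ncol(counts)), colnames(counts))
  }
  structure(list(counts = counts,
                 samples = samples[match(colnames(counts), samples$name), ],
                 unmapped = unmapped[colnames(counts)]),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("<count_table> ", nrow(x$counts), " sgRNAs x ", ncol(x$counts),
      " samples\n", sep = "")
  info <- paste0(x$samples$name, " (", x$samples$role, ")")
  cat("  samples: ", paste(info, collapse = ", "), "\n", sep = "")
  cat("  total mapped: ", paste(colSums(x$counts), collapse = ", "),
      "; unmapped: ", paste(x$unmapped, collapse = ", "), "\n", sep = "")
  invisible(x)
}

samples_by_role <- function(ct, role) {
  ct$samples$name[ct$samples$role == role]
}

#' Write / read a count table as TSV with a YAML sample sidecar
#'
#' The TSV holds `sgrna_id` plus one integer column per sample; sample roles,
#' doublings and unmapped tallies travel in a YAML sidecar (default
#' `<path>.samples.yaml`) so the round trip is lossless.
#'
#' @param table A [count_table()].
#' @param path TSV output path.
#' @param sidecar YAML sidecar path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, path, sidecar = paste0(path, ".samples.yaml")) {
  stopifnot(inherits(table, "count_table"))
  df <- tibble::tibble(sgrna_id = rownames(table$counts))
  for (nm in colnames(table$counts)) df[[nm]] <- table$counts[, nm]
  readr::write_tsv(df, path)
  meta <- list(samples = lapply(seq_len(nrow(table$samples)), function(i) {
    s <- table$samples[i, ]
    list(name = s$name, role = s$role,
         doublings = if (is.na(s$doublings)) NULL else s$doublings,
         unmapped = unname(table$unmapped[s$name]))
  }))
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' @param library The library tibble the counts must align to; sgRNAs missing
#'   from the TSV are filled with 0 (with a warning), sgRNAs absent from the
#'   library are an error.
#' @rdname write_counts
#' @export
read_counts <- function(path, library,
                        sidecar = paste0(path, ".samples.yaml")) {
  validate_library(library)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "sgrna_id") {
    stop("counts TSV must have `sgrna_id` as its first column", call. = FALSE)
  }
  extra <- setdiff(df$sgrna_id, library$sgrna_id)
  if (length(extra) > 0) {
    stop("counts TSV contains sgRNA(s) absent from the library: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  sample_cols <- setdiff(names(df), "sgrna_id")
  for (nm in sample_cols) {
    v <- df[[nm]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
      stop("count column `", nm, "` contains negative, missing or ",
           "non-integer values", call. = FALSE)
    }
  }
  missing <- setdiff(library$sgrna_id, df$sgrna_id)
  if (length(missing) > 0) {
    warning(length(missing), " library sgRNA(s) missing from counts TSV; ",
            "filled with 0", call. = FALSE)
  }
  mat <- matrix(0L, nrow = nrow(library), ncol = length(sample_cols),
                dimnames = list(library$sgrna_id, sample_cols))
  idx <- match(df$sgrna_id, library$sgrna_id)
  for (nm in sample_cols) mat[idx, nm] <- as.integer(df[[nm]])

  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    samples <- dplyr::bind_rows(lapply(meta$samples, function(s) {
      tibble::tibble(name = s$name, role = s$role,
                     doublings = s$doublings %||% NA_real_,
                     unmapped = s$unmapped %||% 0)
    }))
    unmapped <- stats::setNames(samples$unmapped, samples$name)
    count_table(mat, samples[, c("name", "role", "doublings")], unmapped)
  } else {
    warning("no sample sidecar found at ", sidecar,
            "; roles inferred from sample names", call. = FALSE)
    roles <- ifelse(sample_cols %in% c("t0", "untreated", "treated"),
                    sample_cols, "untreated")
    count_table(mat, tibble::tibble(name = sample_cols, role = roles))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
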