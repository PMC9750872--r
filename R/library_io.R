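#' Load an sgRNA library reference from CSV or FASTA
#'
#' The library is the reference against which sequencing reads are counted
#' and sgRNA groups (gene x TSS, non-targeting controls) are formed.
#'
#' CSV dialect: columns `sgrna_id`, `sequence`, `gene`, `tss`,
#' `is_nontargeting` (0/1 or logical). FASTA dialect: one record per sgRNA
#' with header `id|gene|tss|NT` for non-targeting records and `id|gene|tss`
#' otherwise; the sequence line is the protospacer.
#'
#' Invariants enforced on load: unique ids and sequences (duplicates are an
#' error naming the offending records), A/C/G/T alphabet, uniform sequence
#' length, non-targeting records carrying the reserved
#' [nontargeting_label()] in `gene` and `tss`, and at least one non-targeting
#' record (required for downstream normalization).
#'
#' @param path File path.
#' @param format `"csv"` or `"fasta"`; default guessed from the extension.
#' @return A validated library tibble.
#' @export
load_library <- function(path, format = c("auto", "csv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "csv"
  }
  lib <- if (format == "csv") {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("sgrna_id", "sequence", "gene", "tss", "is_nontargeting")
    missing <- setdiff(req, names(x))
    if (length(missing) > 0) {
      stop("library CSV missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x$is_nontargeting <- as.logical(as.integer(x$is_nontargeting))
    tibble::as_tibble(x[, req])
  } else {
    seqs <- Biostrings::readDNAStringSet(path)
    fields <- strsplit(names(seqs), "|", fixed = TRUE)
    n_fields <- lengths(fields)
    if (any(n_fields < 3)) {
      stop("FASTA header(s) not in 'id|gene|tss[|NT]' form: ",
           paste(utils::head(names(seqs)[n_fields < 3], 3), collapse = ", "),
           call. = FALSE)
    }
    tibble::tibble(
      sgrna_id = vapply(fields, `[[`, "", 1),
      sequence = unname(as.character(seqs)),
      gene = vapply(fields, `[[`, "", 2),
      tss = vapply(fields, `[[`, "", 3),
      is_nontargeting = vapply(fields, function(f)
        length(f) >= 4 && f[[4]] == "NT", logical(1))
    )
  }
  lib$sequence <- toupper(lib$sequence)
  validate_library(lib)
  lib
}

#' Write an sgRNA library to CSV or FASTA
#'
#' @param library A library tibble.
#' @param path Output path.
#' @param format `"csv"` (0/1-coded `is_nontargeting`) or `"fasta"`
#'   (`id|gene|tss|NT` headers).
#' @return Invisibly, `path`.
#' @export
write_library <- function(library, path, format = c("csv", "fasta")) {
  format <- match.arg(format)
  validate_library(library)
  if (format == "csv") {
    out <- library
    out$is_nontargeting <- as.integer(out$is_nontargeting)
    readr::write_csv(out, path)
  } else {
    headers <- ifelse(
      library$is_nontargeting,
      paste(library$sgrna_id, library$gene, library$tss, "NT", sep = "|"),
      paste(library$sgrna_id, library$gene, library$tss, sep = "|")
    )
    seqs <- Biostrings::DNAStringSet(library$sequence)
    names(seqs) <- headers
    Biostrings::writeXStringSet(seqs, path)
  }
  invisible(path)
}

validate_library <- function(lib) {
  req <- c("sgrna_id", "sequence", "gene", "tss", "is_nontargeting")
  missing <- setdiff(req, names(lib))
  if (length(missing) > 0) {
    stop("library is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup_id <- lib$sgrna_id[duplicated(lib$sgrna_id)]
  if (length(dup_id) > 0) {
    stop("duplicate sgrna_id(s): ",
         paste(unique(dup_id), collapse = ", "), call. = FALSE)
  }
  dup_seq <- unique(lib$sequence[duplicated(lib$sequence)])
  if (length(dup_seq) > 0) {
    offenders <- lib$sgrna_id[lib$sequence %in% dup_seq]
    stop("duplicate protospacer sequence(s) shared by: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", lib$sequence)
  if (any(bad)) {
    stop("non-ACGT characters in sequence of: ",
         paste(lib$sgrna_id[bad], collapse = ", "), call. = FALSE)
  }
  if (length(unique(nchar(lib$sequence))) != 1L) {
    stop("protospacer sequences are not all the same length", call. = FALSE)
  }
  nt <- lib$is_nontargeting
  if (!any(nt)) {
    stop("library has no non-targeting records; at least one is required ",
         "for normalization", call. = FALSE)
  }
  sentinel <- nontargeting_label()
  bad_nt <- nt & (lib$gene != sentinel | lib$tss != sentinel)
  if (any(bad_nt)) {
    stop("non-targeting record(s) must use gene/tss sentinel '", sentinel,
         "': ", paste(lib$sgrna_id[bad_nt], collapse = ", "), call. = FALSE)
  }
  invisible(lib)
}
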