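#' Count sgRNA-matching reads from FASTQ files
#'
#' Converts raw reads into an sgRNA count table by matching against the
#' library reference. In the primary mode a read increments an sgRNA if and
#' only if the substring `[offset, offset + L)` equals its protospacer
#' exactly (forward strand, no mismatches); all other reads are tallied as
#' unmapped. An optional substring-scan mode searches for the protospacer
#' anywhere in the read; in that mode a read matching more than one sgRNA is
#' discarded and tallied separately.
#'
#' @param samples Tibble with columns `name`, `role`, `path` (FASTQ, plain or
#'   gzipped) and optionally `doublings`, e.g. the return value of
#'   [emit_fastq()]. Several rows may share a role (replicates).
#' @param library The library tibble.
#' @param offset 0-based protospacer offset within each read.
#' @param scan Use substring-scan mode instead of fixed-offset matching.
#' @return A [count_table()]; the attribute `"multihit"` carries the
#'   per-sample tally of multi-matching reads (scan mode only).
#' @export
count_reads <- function(samples, library, offset = 0, scan = FALSE) {
  validate_library(library)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("name", "role", "path") %in% names(samples)))
  L <- nchar(library$sequence[1])

  mat <- matrix(0L, nrow = nrow(library), ncol = nrow(samples),
                dimnames = list(library$sgrna_id, samples$name))
  unmapped <- stats::setNames(numeric(nrow(samples)), samples$name)
  multihit <- stats::setNames(numeric(nrow(samples)), samples$name)

  pdict <- if (scan) Biostrings::PDict(library$sequence) else NULL

  for (s in seq_len(nrow(samples))) {
    reads <- read_fastq_seqs(samples$path[s])
    if (length(reads) == 0) next
    widths <- Biostrings::width(reads)
    if (any(widths < offset + L)) {
      stop("sample `", samples$name[s], "`: ", sum(widths < offset + L),
           " read(s) shorter than offset + protospacer length (",
           offset + L, ")", call. = FALSE)
    }
    if (scan) {
      hits <- Biostrings::vwhichPDict(pdict, reads)
      n_hits <- lengths(hits)
      uniq <- n_hits == 1L
      idx <- unlist(hits[uniq], use.names = FALSE)
      mat[, s] <- mat[, s] + tabulate(idx, nbins = nrow(library))
      unmapped[s] <- unmapped[s] + sum(n_hits == 0L)
      multihit[s] <- multihit[s] + sum(n_hits > 1L)
    } else {
      sub <- as.character(Biostrings::subseq(reads, start = offset + 1,
                                             width = L))
      idx <- match(sub, library$sequence)
      mat[, s] <- mat[, s] + tabulate(idx, nbins = nrow(library))
      unmapped[s] <- unmapped[s] + sum(is.na(idx))
    }
  }

  meta <- samples[, intersect(c("name", "role", "doublings"), names(samples))]
  ct <- count_table(mat, meta, unmapped)
  attr(ct, "multihit") <- multihit
  ct
}

read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  # An empty FASTQ is a legal input (zero-count sample).
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0) return(Biostrings::DNAStringSet())
  tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("failed to parse FASTQ ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
}

#' Per-sample read-mapping statistics
#'
#' @param table A [count_table()] produced by [count_reads()].
#' @return Tibble with `sample`, `total`, `mapped`, `unmapped`, `multihit`.
#' @export
count_stats <- function(table) {
  stopifnot(inherits(table, "count_table"))
  mapped <- colSums(table$counts)
  multihit <- attr(table, "multihit") %||%
    stats::setNames(rep(0, ncol(table$counts)), colnames(table$counts))
  tibble::tibble(
    sample = colnames(table$counts),
    mapped = as.numeric(mapped),
    unmapped = as.numeric(table$unmapped),
    multihit = as.numeric(multihit),
    total = mapped + as.numeric(table$unmapped) + as.numeric(multihit)
  )
}
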