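# FASTQ -> raw sequence-by-sample count table: trim, collapse, rare-read filter.

#' Trim the 3' sequencing adapter off reads
#'
#' Finds the leftmost exact match of the adapter in each read: either the
#' full adapter anywhere, or a terminal partial match of at least
#' \code{min_overlap} adapter-prefix nucleotides ending flush with the
#' read's 3' end. The prefix before the match is returned. Reads with no
#' match, or whose trimmed insert is shorter than 7 nt (too short to carry
#' a seed), come back as \code{NA}.
#'
#' Matching is exact — no mismatch tolerance. Quality scores play no role.
#'
#' @param reads character vector of reads (RNA or DNA alphabet; normalized
#'   internally).
#' @param adapter the 3' adapter sequence.
#' @param min_overlap minimum length of a terminal partial adapter match
#'   (default 4).
#' @return Character vector: trimmed inserts, \code{NA} where untrimmable.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 4L) {
  stopifnot(nchar(adapter) >= 1L, min_overlap >= 1L)
  adapter <- normalize_rna(adapter)
  reads <- normalize_rna(reads)
  # work on unique sequences; FASTQ input repeats them heavily
  uniq <- unique(reads)
  trimmed_uniq <- vapply(uniq, trim_one, character(1L),
                         adapter = adapter, min_overlap = min_overlap,
                         USE.NAMES = FALSE)
  out <- trimmed_uniq[match(reads, uniq)]
  out[!is.na(out) & nchar(out) < 7L] <- NA_character_
  out
}

trim_one <- function(read, adapter, min_overlap) {
  n <- nchar(read)
  m <- nchar(adapter)
  # leftmost full-adapter occurrence
  full_at <- regexpr(adapter, read, fixed = TRUE)
  best <- if (full_at > 0L) as.integer(full_at) else NA_integer_
  # terminal partial match starting after the last full-match window
  start_partial <- max(n - m + 2L, 1L)
  limit <- if (is.na(best)) n - min_overlap + 1L else best - 1L
  if (start_partial <= limit) {
    for (i in start_partial:limit) {
      k <- n - i + 1L
      if (k >= min_overlap &&
          substr(read, i, n) == substr(adapter, 1L, k)) {
        best <- i
        break
      }
    }
  }
  if (is.na(best)) NA_character_ else substr(read, 1L, best - 1L)
}

#' Collapse per-sample read collections into a count table
#'
#' One row per distinct sequence across all samples; each cell is the
#' multiplicity of that sequence in that sample. Row order is
#' deterministic: descending total count, then sequence lexicographic.
#'
#' @param sample_reads named list, one character vector of (trimmed,
#'   alphabet-normalized) reads per sample.
#' @return A tibble with column \code{sequence} followed by one integer
#'   column per sample.
#' @export
collapse_counts <- function(sample_reads) {
  stopifnot(length(sample_reads) >= 1L, !is.null(names(sample_reads)))
  if (anyDuplicated(names(sample_reads))) {
    stop("sample identifiers must be unique", call. = FALSE)
  }
  empty <- vapply(sample_reads, length, integer(1L)) == 0L
  if (any(empty)) {
    warning("sample(s) with zero reads retained as all-zero columns: ",
            paste(names(sample_reads)[empty], collapse = ", "), call. = FALSE)
  }
  seqs <- sort(unique(unlist(sample_reads, use.names = FALSE)))
  counts <- lapply(sample_reads, function(r) {
    tabulate(match(r, seqs), nbins = length(seqs))
  })
  tbl <- tibble::tibble(sequence = seqs, !!!counts)
  order_count_table(tbl)
}

order_count_table <- function(tbl) {
  samples <- count_samples(tbl)
  totals <- if (length(samples)) rowSums(tbl[samples]) else rep(0, nrow(tbl))
  tbl[order(-totals, tbl$sequence), ]
}

# sample columns = everything that is not a known annotation column
ANNOT_COLS <- c("sequence", "rna_type", "match_name", "seed", "viability",
                "name", "mean_control", "mean_perturbed", "delta", "p")

count_samples <- function(tbl) {
  setdiff(names(tbl), ANNOT_COLS)
}

#' Drop rare reads from a count table
#'
#' Retains rows whose total count across all samples is at least
#' \code{min_total}. The threshold applies to the row total, not per
#' sample; the number of rows removed is reported.
#'
#' @param table a count table (\code{sequence} column + sample columns).
#' @param min_total non-negative integer threshold (default 6).
#' @return The filtered table, row order preserved.
#' @export
filter_rare <- function(table, min_total = 6L) {
  stopifnot(min_total >= 0L)
  samples <- count_samples(table)
  totals <- rowSums(table[samples])
  keep <- totals >= min_total
  if (any(!keep)) {
    message(sum(!keep), " rare read(s) removed (row total < ", min_total, ")")
  }
  table[keep, ]
}

#' Read per-sample FASTQ files into a raw count table
#'
#' The full preprocessing stage: reads each sample's FASTQ (plain or
#' gzipped), trims the 3' adapter, drops untrimmable and sub-7-nt reads
#' (reported per sample), collapses to a sequence-by-sample count table
#' and applies the rare-read filter.
#'
#' @param files named character vector of FASTQ paths; names are sample
#'   identifiers.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum terminal adapter overlap for trimming.
#' @param min_total rare-read row-total threshold.
#' @return A raw count table tibble.
#' @export
fastq_to_counts <- function(files, adapter, min_overlap = 4L, min_total = 6L) {
  stopifnot(length(files) >= 1L, !is.null(names(files)))
  sample_reads <- lapply(files, function(f) {
    reads <- as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
    trimmed <- trim_adapter(reads, adapter, min_overlap)
    dropped <- sum(is.na(trimmed))
    if (dropped > 0L) {
      message(basename(f), ": ", dropped,
              " read(s) untrimmable or < 7 nt, dropped")
    }
    trimmed[!is.na(trimmed)]
  })
  filter_rare(collapse_counts(sample_reads), min_total)
}

#' Write / read a count table as TSV
#'
#' First column \code{sequence}, one column per sample (plus any
#' annotation columns), tab-separated, header row.
#'
#' @param table count table tibble.
#' @param path TSV path.
#' @return \code{write_count_table}: \code{path} invisibly;
#'   \code{read_count_table}: the tibble.
#' @export
write_count_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
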