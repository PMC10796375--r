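# Seed-sequence primitives and the 6mer viability lookup.

RNA_NUCS <- c("A", "C", "G", "U")

#' Enumerate all 4096 6mer seeds
#'
#' All 4^6 = 4096 sequences of length 6 over the RNA alphabet
#' \{A, C, G, U\}, in lexicographic order.
#'
#' @return Character vector of length 4096.
#' @export
all_seeds <- function() {
  grid <- expand.grid(rep(list(RNA_NUCS), 6L),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(do.call(paste0, grid))
}

#' Normalize nucleotide strings to the RNA alphabet
#'
#' Uppercases and maps T to U. Used at every ingestion point so that all
#' downstream sequence keys live in one alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return Character vector in \{A, C, G, U\}.
#' @export
normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("bad alphabet: ", what, " contains characters outside {A,C,G,U}: ",
         paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Extract the 6mer seed (positions 2-7) of a guide-strand read
#'
#' The seed of a small RNA is defined as nucleotides 2-7 (1-based) of the
#' 5'->3' guide strand. Reads are normalized to the RNA alphabet first, so
#' DNA-space sequencing reads and RNA-space seed nomenclature mix freely.
#'
#' @param read character vector of reads, length >= 7 nt each, over
#'   \{A,C,G,T,U\} in either case.
#' @return Character vector of 6mer seeds over \{A,C,G,U\}.
#' @examples
#' extract_seed("UGGCAGUGUCUUAGCUGGUUGU")  # "GGCAGU", the miR-34a-5p seed
#' @export
extract_seed <- function(read) {
  read <- normalize_rna(read)
  short <- !is.na(read) & nchar(read) < 7L
  if (any(short)) {
    stop("read too short: ", sum(short), " read(s) under 7 nt (seed needs positions 2-7)",
         call. = FALSE)
  }
  check_rna_alphabet(read, "read")
  substr(read, 2L, 7L)
}

#' Build a validated 6mer viability table
#'
#' A viability table maps every one of the 4096 6mer seeds to the percent
#' viability of cells carrying that seed in an siRNA-like backbone, measured
#' in three human and three mouse cell lines. Per-species averages (plain
#' arithmetic mean of the three cell lines) are derived on construction.
#'
#' @param df data frame with a seed column and six numeric cell-line
#'   columns.
#' @param seed_col name of the seed column.
#' @param human_cols,mouse_cols names of the three human / three mouse
#'   cell-line viability columns.
#' @return A tibble of class \code{viability_table} with columns
#'   \code{seed}, the six cell-line columns, \code{human_avg},
#'   \code{mouse_avg}. Exactly 4096 rows, one per possible seed.
#' @export
viability_table <- function(df, seed_col = "seed",
                            human_cols = c("human1", "human2", "human3"),
                            mouse_cols = c("mouse1", "mouse2", "mouse3")) {
  cols <- c(seed_col, human_cols, mouse_cols)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("viability table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seeds <- normalize_rna(as.character(df[[seed_col]]))
  if (anyDuplicated(seeds)) {
    stop("duplicate seed(s) in viability table: ",
         paste(utils::head(unique(seeds[duplicated(seeds)]), 3L), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(seeds) != 6L)) {
    stop("viability table seed(s) not 6 nt: row ",
         which(nchar(seeds) != 6L)[1L], call. = FALSE)
  }
  check_rna_alphabet(seeds, "seed")
  absent <- setdiff(all_seeds(), seeds)
  if (length(absent)) {
    stop("incomplete viability table: ", length(absent),
         " of 4096 seeds absent, e.g. ", paste(utils::head(absent, 3L), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[c(human_cols, mouse_cols)]
  if (!all(vapply(vals, is.numeric, logical(1L)))) {
    stop("viability columns must be numeric", call. = FALSE)
  }
  if (any(is.na(as.matrix(vals))) || any(as.matrix(vals) < 0)) {
    stop("viability values must be >= 0 and non-missing (values > 100 are legal)",
         call. = FALSE)
  }
  out <- tibble::tibble(seed = seeds)
  out[c(paste0("human", 1:3), paste0("mouse", 1:3))] <-
    df[c(human_cols, mouse_cols)]
  out$human_avg <- rowMeans(out[paste0("human", 1:3)])
  out$mouse_avg <- rowMeans(out[paste0("mouse", 1:3)])
  out <- out[order(out$seed), ]
  class(out) <- c("viability_table", class(out))
  out
}

#' Look up the species-average viability of seeds
#'
#' Returns the arithmetic mean percent viability of the three cell lines of
#' the requested species, on the printed percent scale (e.g. 40.0, not 0.40).
#'
#' @param seed character vector of 6mer seeds.
#' @param species \code{"human"} or \code{"mouse"}; pick the species of the
#'   cells or tissue being analyzed.
#' @param table a \code{\link{viability_table}}.
#' @return Numeric vector of percent viabilities.
#' @export
seed_viability <- function(seed, species = c("human", "mouse"), table) {
  species <- match.arg(species)
  seed <- normalize_rna(seed)
  idx <- match(seed, table$seed)
  if (anyNA(idx)) {
    stop("incomplete viability table: seed(s) absent: ",
         paste(utils::head(unique(seed[is.na(idx)]), 3L), collapse = ", "),
         call. = FALSE)
  }
  table[[paste0(species, "_avg")]][idx]
}

#' Read a 6mer viability lookup table from CSV
#'
#' Expects a header row and one row per seed: the seed column (RNA
#' alphabet) plus three human and three mouse cell-line viability columns.
#' Completeness (all 4096 seeds), alphabet and non-negativity are enforced.
#'
#' @inheritParams viability_table
#' @param path path to the CSV file.
#' @return A \code{\link{viability_table}}.
#' @export
load_viability_table <- function(path, seed_col = "seed",
                                 human_cols = c("human1", "human2", "human3"),
                                 mouse_cols = c("mouse1", "mouse2", "mouse3")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  viability_table(df, seed_col = seed_col,
                  human_cols = human_cols, mouse_cols = mouse_cols)
}

#' Write a viability table to CSV
#'
#' @param table a \code{\link{viability_table}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_viability_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table)[c("seed", paste0("human", 1:3),
                                              paste0("mouse", 1:3))],
                   path, progress = FALSE)
  invisible(path)
}
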