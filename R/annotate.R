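# RNA-type assignment against reference sets; seed + viability annotation.

#' Load a reference sequence set from FASTA
#'
#' Reads a multi-record FASTA (DNA or RNA alphabet), normalizes sequences
#' to the RNA alphabet and checks name uniqueness. Only the first
#' whitespace-delimited token of each FASTA header is kept as the name.
#'
#' @param path FASTA path.
#' @param name set label: \code{"artificial"}, \code{"miRNA"} or
#'   \code{"RNAworld"}.
#' @return A \code{reference_set}: list with \code{name} and a named
#'   character vector \code{sequences}.
#' @export
load_reference_set <- function(path, name = c("artificial", "miRNA", "RNAworld")) {
  name <- match.arg(name)
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- normalize_rna(as.character(recs))
  names(seqs) <- sub("\\s.*$", "", names(recs))
  reference_set(seqs, name)
}

#' Construct a reference set from named sequences
#'
#' @param sequences named character vector of reference sequences.
#' @param name set label.
#' @return A \code{reference_set} object.
#' @export
reference_set <- function(sequences, name = c("artificial", "miRNA", "RNAworld")) {
  name <- match.arg(name)
  sequences <- normalize_rna(sequences)
  check_rna_alphabet(sequences, paste(name, "reference"))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reference sequence names must be present and unique within the ",
         name, " set", call. = FALSE)
  }
  structure(list(name = name, sequences = sequences), class = "reference_set")
}

#' Bundle reference sets in matching priority order
#'
#' Reads are matched against artificial sequences first, then mature
#' miRNAs, then the RNAworld catch-all of other small RNAs; the first set
#' containing the read wins. Any set may be omitted.
#'
#' @param artificial,mirna,rnaworld \code{reference_set} objects or NULL.
#' @return An ordered list of reference sets.
#' @export
reference_sets <- function(artificial = NULL, mirna = NULL, rnaworld = NULL) {
  refs <- list(artificial = artificial, miRNA = mirna, RNAworld = rnaworld)
  refs <- refs[!vapply(refs, is.null, logical(1L))]
  for (nm in names(refs)) {
    if (!inherits(refs[[nm]], "reference_set") || refs[[nm]]$name != nm) {
      stop("slot '", nm, "' must hold a reference_set labeled '", nm, "'",
           call. = FALSE)
    }
  }
  refs
}

#' Match reads against prioritized reference sets
#'
#' A read matches a set when it occurs as an exact substring of any
#' reference sequence in that set (exact identity included). Sets are
#' tried in priority order (artificial > miRNA > RNAworld); within a set,
#' ties resolve to the first reference in file order. Reads matching no
#' set are \code{("unknown", "")}.
#'
#' This is deliberately exact — a membership check against curated lists —
#' with no mismatch tolerance.
#'
#' @param reads character vector of reads (RNA alphabet).
#' @param refs ordered list from \code{\link{reference_sets}}.
#' @return A tibble with columns \code{rna_type} and \code{match_name},
#'   one row per read.
#' @export
match_read <- function(reads, refs) {
  reads <- normalize_rna(reads)
  rna_type <- rep("unknown", length(reads))
  match_name <- rep("", length(reads))
  pending <- rep(TRUE, length(reads))
  for (set in refs) {
    if (!any(pending)) break
    idx <- which(pending)
    hit <- vapply(reads[idx], function(r) {
      w <- which(vapply(set$sequences, grepl, logical(1L), pattern = r,
                        fixed = TRUE))
      if (length(w)) w[1L] else NA_integer_
    }, integer(1L), USE.NAMES = FALSE)
    found <- !is.na(hit)
    rna_type[idx[found]] <- set$name
    match_name[idx[found]] <- names(set$sequences)[hit[found]]
    pending[idx[found]] <- FALSE
  }
  tibble::tibble(rna_type = rna_type, match_name = match_name)
}

#' Annotate a raw count table with RNA type, seed and viability
#'
#' Rows shorter than 7 nt are removed (no seed), rows matching the
#' artificial reference set are removed, and every surviving row gains
#' \code{rna_type}, \code{match_name}, \code{seed} (read positions 2-7)
#' and \code{viability} (the species-average percent viability of that
#' seed). Count values are never altered. Rows typed \code{unknown} are
#' retained: the analysis is gene-agnostic and needs only the seed.
#'
#' @param table raw count table (\code{sequence} + sample columns).
#' @param refs ordered reference sets (\code{\link{reference_sets}}).
#' @param species \code{"human"} or \code{"mouse"}.
#' @param viab a \code{\link{viability_table}}.
#' @return Annotated count table tibble.
#' @export
annotate_table <- function(table, refs, species = c("human", "mouse"), viab) {
  species <- match.arg(species)
  table$sequence <- normalize_rna(table$sequence)
  short <- nchar(table$sequence) < 7L
  if (any(short)) {
    message(sum(short), " row(s) with reads < 7 nt removed")
    table <- table[!short, ]
  }
  m <- match_read(table$sequence, refs)
  artificial <- m$rna_type == "artificial"
  if (any(artificial)) {
    message(sum(artificial), " row(s) matching artificial sequences removed")
  }
  table <- table[!artificial, ]
  m <- m[!artificial, ]
  table$rna_type <- m$rna_type
  table$match_name <- m$match_name
  table$seed <- extract_seed(table$sequence)
  table$viability <- seed_viability(table$seed, species, viab)
  table
}

#' Annotate a published miRNA list by name
#'
#' Entry mode for reanalyzing differential miRNA lists from other studies:
#' each miRNA name is resolved to its mature sequence in the miRNA
#' reference set, the seed is positions 2-7 of that sequence, and the
#' supplied values (e.g. expression changes) become the single count
#' column \code{value}.
#'
#' @param names_and_values data frame with columns \code{name} and
#'   \code{value}, or path to a 2-column CSV with that header.
#' @param mirna_ref \code{reference_set} of mature miRNAs.
#' @param species \code{"human"} or \code{"mouse"}.
#' @param viab a \code{\link{viability_table}}.
#' @return Annotated table with columns \code{sequence}, \code{name},
#'   \code{value}, \code{rna_type}, \code{match_name}, \code{seed},
#'   \code{viability}.
#' @export
annotate_mirna_list <- function(names_and_values, mirna_ref,
                                species = c("human", "mouse"), viab) {
  species <- match.arg(species)
  if (is.character(names_and_values) && length(names_and_values) == 1L) {
    names_and_values <- readr::read_csv(names_and_values,
                                        show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c("name", "value") %in% names(names_and_values)))
  nm <- as.character(names_and_values$name)
  idx <- match(nm, names(mirna_ref$sequences))
  if (anyNA(idx)) {
    stop("miRNA name(s) not in reference: ",
         paste(unique(nm[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(mirna_ref$sequences[idx])
  tibble::tibble(
    sequence = seqs,
    name = nm,
    value = as.numeric(names_and_values$value),
    rna_type = "miRNA",
    match_name = nm,
    seed = extract_seed(seqs),
    viability = seed_viability(extract_seed(seqs), species, viab)
  )
}
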