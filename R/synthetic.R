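# Synthetic data with ground truth: viability lookup, two-group count
# tables with a controlled seed-viability shift, reference FASTA sets,
# and FASTQ fixtures.

#' Simulation configuration
#'
#' Parameters of the synthetic two-group Ago-pulldown-style experiment.
#' The perturbed group's abundances are tilted toward low-viability
#' (G-rich) seeds with strength \code{shift}; \code{shift = 0} makes the
#' groups exchangeable, positive shift pushes the perturbed group's
#' weighted median viability below the control's.
#'
#' @param rng_seed integer seed driving every random draw.
#' @param n_rows number of distinct read sequences.
#' @param samples_per_group samples per group, >= 2 (the differential
#'   stage needs within-group variance).
#' @param depth expected raw reads per sample.
#' @param shift real in [-1, 1]: strength of the low-viability enrichment
#'   in the perturbed group.
#' @param species \code{"human"} or \code{"mouse"}.
#' @param fraction_mirna,fraction_rnaworld,fraction_artificial expected
#'   fractions of rows of each RNA type (the remainder is unannotated);
#'   each in [0,1], summing to <= 1.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(rng_seed = 1L, n_rows = 500L, samples_per_group = 3L,
                       depth = 1e6, shift = 0, species = c("human", "mouse"),
                       fraction_mirna = 0.6, fraction_rnaworld = 0.2,
                       fraction_artificial = 0.05) {
  species <- match.arg(species)
  fr <- c(fraction_mirna, fraction_rnaworld, fraction_artificial)
  stopifnot(n_rows >= 1L, depth > 0, shift >= -1, shift <= 1,
            all(fr >= 0), all(fr <= 1), sum(fr) <= 1)
  if (samples_per_group < 2L) {
    stop("samples_per_group must be >= 2 (differential stage precondition)",
         call. = FALSE)
  }
  structure(list(rng_seed = as.integer(rng_seed), n_rows = as.integer(n_rows),
                 samples_per_group = as.integer(samples_per_group),
                 depth = depth, shift = shift, species = species,
                 fraction_mirna = fraction_mirna,
                 fraction_rnaworld = fraction_rnaworld,
                 fraction_artificial = fraction_artificial),
            class = "sim_config")
}

# Deterministic toxicity backbone: viability decreases monotonically with a
# G/C-weighted content score of the seed (G weighted above C), emulating
# the G-rich = toxic structure of the measured seed screen.
seed_base_viability <- function(seed) {
  chars <- strsplit(seed, "", fixed = TRUE)
  score <- vapply(chars, function(ch) {
    sum((ch == "G") * 1 + (ch == "C") * 0.45) / 6
  }, numeric(1L))
  112 - 92 * score
}

#' Generate a complete synthetic 6mer viability table
#'
#' All 4096 seeds; each cell-line viability is a seed-specific base value
#' plus Gaussian noise, clipped at 0. The base decreases monotonically
#' with a G/C-weighted content score (G above C), so G-rich seeds are
#' toxic and A/U-rich seeds can exceed 100% (growth-enhancing), mirroring
#' the qualitative structure of the measured screen. Values are synthetic,
#' not measurements.
#'
#' @param rng_seed integer seed; identical seeds give identical tables.
#' @param noise_sd standard deviation of the per-cell-line noise, in
#'   percent viability.
#' @return A \code{\link{viability_table}}.
#' @export
gen_viability_table <- function(rng_seed = 1L, noise_sd = 8) {
  set.seed(as.integer(rng_seed))
  seeds <- all_seeds()
  base <- seed_base_viability(seeds)
  df <- tibble::tibble(seed = seeds)
  for (col in c(paste0("human", 1:3), paste0("mouse", 1:3))) {
    df[[col]] <- pmax(0, base + stats::rnorm(length(seeds), 0, noise_sd))
  }
  viability_table(df)
}

random_rna <- function(n_chars) {
  paste(sample(RNA_NUCS, n_chars, replace = TRUE), collapse = "")
}

# a read embedding `seed` at positions 2-7, total length in 18..24
embed_seed <- function(seed) {
  len <- sample(18:24, 1L)
  paste0(random_rna(1L), seed, random_rna(len - 7L))
}

#' Generate a two-group raw count table with ground truth
#'
#' Draws \code{n_rows} synthetic read sequences embedding random seeds at
#' positions 2-7, assigns RNA types by the configured fractions, gives
#' rows heavy-tailed (log-normal) baseline abundances, tilts the
#' perturbed group's abundances toward low-viability seeds with strength
#' \code{shift}, and samples integer counts per sample from a Poisson
#' around the group means scaled to \code{depth}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param viab a \code{\link{viability_table}} for the configured species.
#' @return List with \code{table} (raw count table; samples
#'   \code{control_1..k}, \code{perturbed_1..k}) and \code{truth} (per-row
#'   seed, RNA type, viability and expected group-mean counts, plus the
#'   injected shift as attribute \code{"shift"}).
#' @export
gen_counts <- function(cfg, viab) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  n <- cfg$n_rows
  seeds <- sample(viab$seed, n, replace = TRUE)
  seqs <- vapply(seeds, embed_seed, character(1L), USE.NAMES = FALSE)
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(seeds[dup], embed_seed, character(1L), USE.NAMES = FALSE)
  }
  type_probs <- c(miRNA = cfg$fraction_mirna, RNAworld = cfg$fraction_rnaworld,
                  artificial = cfg$fraction_artificial)
  type_probs <- c(type_probs, unknown = 1 - sum(type_probs))
  rna_type <- sample(names(type_probs), n, replace = TRUE, prob = type_probs)
  # no non-artificial read may be a substring of an artificial decoy, or the
  # annotation stage would remove more than the planted rows
  art <- which(rna_type == "artificial")
  if (length(art)) {
    repeat {
      clash <- vapply(seq_len(n), function(i) {
        if (rna_type[i] == "artificial") return(FALSE)
        any(vapply(seqs[art], grepl, logical(1L), pattern = seqs[i],
                   fixed = TRUE))
      }, logical(1L))
      if (!any(clash)) break
      seqs[clash] <- vapply(seeds[clash], embed_seed, character(1L),
                            USE.NAMES = FALSE)
    }
  }
  viability <- seed_viability(seeds, cfg$species, viab)
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 1.5)
  tilt <- exp(cfg$shift * 2.5 * (100 - viability) / 100)
  mean_control <- baseline / sum(baseline) * cfg$depth
  mean_perturbed <- baseline * tilt / sum(baseline * tilt) * cfg$depth
  k <- cfg$samples_per_group
  tbl <- tibble::tibble(sequence = seqs)
  for (j in seq_len(k)) {
    tbl[[paste0("control_", j)]] <- stats::rpois(n, mean_control)
  }
  for (j in seq_len(k)) {
    tbl[[paste0("perturbed_", j)]] <- stats::rpois(n, mean_perturbed)
  }
  truth <- tibble::tibble(sequence = seqs, seed = seeds, rna_type = rna_type,
                          viability = viability,
                          mean_control = mean_control,
                          mean_perturbed = mean_perturbed)
  attr(truth, "shift") <- cfg$shift
  attr(truth, "expected_median_sign") <-
    if (cfg$shift > 0) -1L else if (cfg$shift < 0) 1L else 0L
  list(table = order_count_table(tbl), truth = truth)
}

#' Generate matching reference sets (and optional FASTA files)
#'
#' Builds the three reference sets the annotation stage expects, from a
#' simulation's ground truth: every miRNA-typed row's sequence under a
#' synthetic name; longer RNAworld host sequences containing the
#' RNAworld-typed rows; and the artificial-typed rows themselves as
#' adapter-like decoys. Rows typed \code{unknown} appear in no set.
#'
#' @param truth the \code{truth} tibble from \code{\link{gen_counts}}.
#' @param rng_seed integer seed (for the RNAworld host flanks).
#' @param dir if non-NULL, write \code{mirna.fasta},
#'   \code{rnaworld.fasta}, \code{artificial.fasta} there.
#' @return Ordered reference sets (see \code{\link{reference_sets}});
#'   when \code{dir} is given, file paths are attached as attribute
#'   \code{"paths"}.
#' @export
gen_references <- function(truth, rng_seed = 1L, dir = NULL) {
  set.seed(as.integer(rng_seed))
  pick <- function(type) truth$sequence[truth$rna_type == type]
  mir <- pick("miRNA")
  names(mir) <- sprintf("syn-mir-%04d", seq_along(mir))
  world <- vapply(pick("RNAworld"), function(s) {
    paste0(random_rna(sample(8:12, 1L)), s, random_rna(sample(8:12, 1L)))
  }, character(1L), USE.NAMES = FALSE)
  names(world) <- sprintf("syn-rnaworld-%04d", seq_along(world))
  art <- pick("artificial")
  names(art) <- sprintf("syn-artificial-%04d", seq_along(art))
  for (m in mir) {
    if (any(vapply(art, grepl, logical(1L), pattern = m, fixed = TRUE))) {
      stop("generator constraint violated: a miRNA reference is contained ",
           "in an artificial decoy", call. = FALSE)
    }
  }
  refs <- reference_sets(
    artificial = reference_set(art, "artificial"),
    mirna = reference_set(mir, "miRNA"),
    rnaworld = reference_set(world, "RNAworld")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(artificial = file.path(dir, "artificial.fasta"),
               miRNA = file.path(dir, "mirna.fasta"),
               RNAworld = file.path(dir, "rnaworld.fasta"))
    for (nm in names(refs)) {
      Biostrings::writeXStringSet(
        Biostrings::RNAStringSet(refs[[nm]]$sequences), paths[[nm]])
    }
    attr(refs, "paths") <- paths
  }
  refs
}

#' Write per-sample FASTQ files realizing a count table
#'
#' Each row's sequence (back in DNA alphabet, with the 3' adapter
#' appended) is replicated per its count in each sample, shuffled
#' deterministically, and written as a 4-line-record FASTQ. Running
#' \code{\link{fastq_to_counts}} on the output with the same adapter
#' reproduces the table exactly (for tables that pass the rare-read
#' filter).
#'
#' @param table raw count table.
#' @param adapter 3' adapter sequence to append.
#' @param dir output directory (created if needed).
#' @param rng_seed integer seed for the read shuffle.
#' @return Named character vector of FASTQ paths, one per sample.
#' @export
gen_fastq <- function(table, adapter, dir, rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- count_samples(table)
  paths <- setNames(file.path(dir, paste0(samples, ".fastq")), samples)
  for (s in samples) {
    reads <- rep(table$sequence, table[[s]])
    if (length(reads)) {
      reads <- sample(reads)
      reads <- paste0(reads, adapter)
    }
    recs <- Biostrings::DNAStringSet(chartr("U", "T", reads))
    if (length(recs)) {
      names(recs) <- paste0(s, ":", seq_along(recs))
    }
    Biostrings::writeXStringSet(recs, paths[[s]], format = "fastq")
  }
  paths
}
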