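# Orchestration: configuration, the full count-table pipeline, and the
# miRNA-list entry mode.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the full pipeline. Samples must
#' each belong to exactly one group.
#'
#' @param species \code{"human"} or \code{"mouse"}.
#' @param groups named character vector: sample name -> group label
#'   (exactly two distinct labels).
#' @param control_group,perturbed_group the two group labels.
#' @param adapter 3' adapter sequence (used when input is FASTQ).
#' @param min_overlap minimum terminal adapter overlap.
#' @param min_total rare-read row-total threshold.
#' @param alpha differential significance threshold.
#' @param divisor expansion divisor.
#' @param bin_width viability bin width in percent.
#' @param rng_seed integer seed recorded in the manifest.
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(species = c("human", "mouse"), groups,
                            control_group = "control",
                            perturbed_group = "perturbed",
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            min_overlap = 4L, min_total = 6L, alpha = 0.05,
                            divisor = 1000, bin_width = 1, rng_seed = 1L) {
  species <- match.arg(species)
  if (is.null(names(groups)) || anyDuplicated(names(groups))) {
    stop("groups must be a named vector: each sample in exactly one group",
         call. = FALSE)
  }
  labels <- unique(groups)
  if (!setequal(labels, c(control_group, perturbed_group))) {
    stop("group labels must be exactly {", control_group, ", ",
         perturbed_group, "}; got {", paste(labels, collapse = ", "), "}",
         call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, divisor >= 1, bin_width > 0,
            min_total >= 0, min_overlap >= 1)
  structure(list(species = species, groups = groups,
                 control_group = control_group,
                 perturbed_group = perturbed_group,
                 adapter = normalize_rna(adapter),
                 min_overlap = as.integer(min_overlap),
                 min_total = as.integer(min_total), alpha = alpha,
                 divisor = divisor, bin_width = bin_width,
                 rng_seed = as.integer(rng_seed),
                 quantile_convention = "linear interpolation (type 7)",
                 test = "two-sided equal-variance Student's t-test"),
            class = "pipeline_config")
}

box_stats_row <- function(bs, label) {
  tibble::tibble(group = label, median = bs$median, q1 = bs$q1, q3 = bs$q3,
                 whisker_low = bs$whisker_low, whisker_high = bs$whisker_high,
                 n_outliers = length(bs$outliers), n = bs$n)
}

composition_tsv <- function(mat) {
  tibble::tibble(nucleotide = rownames(mat), tibble::as_tibble(mat))
}

#' Run the full count-table pipeline
#'
#' Orchestrates every stage: preprocessing (or validation of a supplied
#' raw count table), annotation, normalization, differential selection,
#' and the weighted viability statistics in both of the two modes — (a)
#' total R-sRNA mode, expanding each group's mean normalized counts, and
#' (b) differential mode, expanding |delta| of enriched and depleted rows
#' separately. All tables are written as TSV under \code{outdir}, along
#' with a run manifest (every config value, input checksums, package
#' version). Outputs are a pure function of config + inputs: identical
#' runs give byte-identical files.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param refs ordered reference sets (\code{\link{reference_sets}}).
#' @param viab a \code{\link{viability_table}}.
#' @param outdir output directory (created).
#' @param fastq named vector of per-sample FASTQ paths, or NULL.
#' @param count_table a raw count table tibble or TSV path, or NULL.
#'   Exactly one of \code{fastq} / \code{count_table} must be given.
#' @return Invisibly, a list with the main in-memory results:
#'   \code{raw}, \code{annotated}, \code{norm}, \code{differential},
#'   \code{box}, \code{kruskal}, \code{curves}, \code{composition},
#'   \code{files}.
#' @export
run_full <- function(config, refs, viab, outdir, fastq = NULL,
                     count_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(fastq) == is.null(count_table)) {
    stop("give exactly one of fastq= or count_table=", call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(outdir, name)
    write_count_table(tbl, path)
    written <<- c(written, path)
    path
  }
  stage <- "input"
  on.exit({
    if (!is.null(stage)) {
      unlink(written)
      message("pipeline aborted at stage: ", stage, "; partial outputs removed")
    }
  })

  input_paths <- c(fastq, if (is.character(count_table)) count_table)
  if (!is.null(fastq)) {
    stage <- "preprocess"
    raw <- fastq_to_counts(fastq, config$adapter, config$min_overlap,
                           config$min_total)
  } else {
    if (is.character(count_table)) count_table <- read_count_table(count_table)
    raw <- filter_rare(order_count_table(count_table), config$min_total)
  }
  stage <- "validate"
  samples <- count_samples(raw)
  unknown <- setdiff(names(config$groups), samples)
  if (length(unknown)) {
    stop("config groups name sample(s) absent from the data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw <- raw[c("sequence", names(config$groups))]
  emit(raw, "rawCounts.tsv")

  stage <- "annotate"
  annotated <- annotate_table(raw, refs, config$species, viab)
  emit(annotated, "annotatedCounts.tsv")

  stage <- "normalize"
  norm <- normalize_counts(annotated)
  emit(norm, "normCounts.tsv")

  stage <- "differential"
  diff <- differential(norm, config$groups, config$control_group,
                       config$perturbed_group, config$alpha)
  emit(diff, "differential.tsv")

  stage <- "viability statistics"
  ctrl_samples <- names(config$groups)[config$groups == config$control_group]
  pert_samples <- names(config$groups)[config$groups == config$perturbed_group]
  norm$mean_control <- rowMeans(norm[ctrl_samples])
  norm$mean_perturbed <- rowMeans(norm[pert_samples])
  ev_total <- list()
  ev_total[[config$control_group]] <-
    expand_viability(norm$viability, norm$mean_control, config$divisor)
  ev_total[[config$perturbed_group]] <-
    expand_viability(norm$viability, norm$mean_perturbed, config$divisor)
  ev_diff <- list(
    enriched = expand_viability(diff$viability[diff$delta > 0],
                                diff$delta[diff$delta > 0], config$divisor),
    depleted = expand_viability(diff$viability[diff$delta < 0],
                                abs(diff$delta[diff$delta < 0]), config$divisor)
  )
  box <- dplyr::bind_rows(c(
    lapply(names(ev_total), function(g) box_stats_row(box_stats(ev_total[[g]]),
                                                      paste0("total_", g))),
    lapply(names(ev_diff)[lengths(ev_diff) > 0],
           function(g) box_stats_row(box_stats(ev_diff[[g]]),
                                     paste0("differential_", g)))
  ))
  kw <- list(total = compare_groups(ev_total),
             differential = if (all(lengths(ev_diff) > 0)) {
               compare_groups(ev_diff)
             })
  box$kruskal_p <- c(rep(kw$total$p, 2L),
                     rep(if (is.null(kw$differential)) NA_real_ else
                       kw$differential$p, sum(lengths(ev_diff) > 0)))
  emit(box, "boxStats.tsv")

  curve_ctrl <- binned_curve(norm, "mean_control", config$bin_width,
                             by_type = TRUE)
  curve_pert <- binned_curve(norm, "mean_perturbed", config$bin_width,
                             by_type = TRUE)
  curve_ctrl$group <- paste0("total_", config$control_group)
  curve_pert$group <- paste0("total_", config$perturbed_group)
  curves <- dplyr::bind_rows(curve_ctrl, curve_pert)
  emit(curves, "viabilityCurve_total.tsv")
  curve_diff <- binned_curve_differential(diff, config$bin_width)
  emit(curve_diff, "viabilityCurve_differential.tsv")

  comp <- list(
    total_control = seed_composition(norm, "mean_control", config$divisor),
    total_perturbed = seed_composition(norm, "mean_perturbed", config$divisor)
  )
  if (any(diff$delta > 0)) {
    enr <- diff[diff$delta > 0, ]
    comp$differential_enriched <- seed_composition(enr, "delta", config$divisor)
  }
  if (any(diff$delta < 0)) {
    dep <- diff[diff$delta < 0, ]
    dep$abs_delta <- abs(dep$delta)
    comp$differential_depleted <- seed_composition(dep, "abs_delta",
                                                   config$divisor)
  }
  comp_tbl <- dplyr::bind_rows(lapply(names(comp), function(nm) {
    out <- composition_tsv(comp[[nm]])
    out$series <- nm
    out[c("series", setdiff(names(out), "series"))]
  }))
  emit(comp_tbl, "seedComposition.tsv")

  stage <- "manifest"
  manifest <- list(
    package = "sixmer",
    version = as.character(utils::packageVersion("sixmer")),
    config = config[setdiff(names(config), NULL)],
    inputs = as.list(if (length(input_paths)) {
      tools::md5sum(input_paths)
    } else setNames(character(0), character(0))),
    outputs = basename(written)
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  written <- c(written, manifest_path)
  stage <- NULL  # success: keep outputs

  invisible(list(raw = raw, annotated = annotated, norm = norm,
                 differential = diff, expanded = c(ev_total, ev_diff),
                 box = box, kruskal = kw,
                 curves = list(total = curves, differential = curve_diff),
                 composition = comp, files = written))
}

#' Run the miRNA-list entry mode
#'
#' Reanalysis of a published differential miRNA list: names are resolved
#' to mature sequences, annotated with seed and viability, then split by
#' the sign of \code{value} into up- and downregulated directions. Each
#' direction gets |value|-weighted box statistics and a seed-composition
#' matrix; when both directions are present they are compared with the
#' Kruskal-Wallis test.
#'
#' @param names_and_values data frame (\code{name}, \code{value}) or CSV
#'   path; positive values = upregulated, negative = downregulated.
#' @param mirna_ref \code{reference_set} of mature miRNAs.
#' @param viab a \code{\link{viability_table}}.
#' @param species \code{"human"} or \code{"mouse"}.
#' @param outdir if non-NULL, write annotated table, box stats and
#'   composition matrices there as TSV.
#' @param divisor expansion divisor.
#' @return List with \code{annotated}, \code{box}, \code{kruskal},
#'   \code{composition}.
#' @export
run_mirna_list <- function(names_and_values, mirna_ref, viab,
                           species = c("human", "mouse"), outdir = NULL,
                           divisor = 1) {
  species <- match.arg(species)
  ann <- annotate_mirna_list(names_and_values, mirna_ref, species, viab)
  dirs <- list(up = ann[ann$value > 0, ], down = ann[ann$value < 0, ])
  dirs <- dirs[vapply(dirs, nrow, integer(1L)) > 0]
  ev <- lapply(dirs, function(d) {
    expand_viability(d$viability, abs(d$value), divisor)
  })
  ev <- ev[lengths(ev) > 0]
  box <- dplyr::bind_rows(lapply(names(ev), function(nm) {
    box_stats_row(box_stats(ev[[nm]]), nm)
  }))
  kw <- if (length(ev) >= 2L) compare_groups(ev)
  comp <- lapply(dirs, function(d) {
    d$abs_value <- abs(d$value)
    seed_composition(d, "abs_value", divisor)
  })
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_count_table(ann, file.path(outdir, "mirnaList_annotated.tsv"))
    if (!is.null(kw)) box$kruskal_p <- kw$p
    write_count_table(box, file.path(outdir, "mirnaList_boxStats.tsv"))
    comp_tbl <- dplyr::bind_rows(lapply(names(comp), function(nm) {
      out <- composition_tsv(comp[[nm]])
      out$series <- nm
      out[c("series", setdiff(names(out), "series"))]
    }))
    write_count_table(comp_tbl, file.path(outdir, "mirnaList_composition.tsv"))
  }
  list(annotated = ann, box = box, kruskal = kw, composition = comp)
}
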