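# Count-weighted viability statistics: expansion, box stats, group
# comparison, binned curves, seed composition.

round_half_up <- function(x) floor(x + 0.5)

expansion_copies <- function(weights, divisor) {
  stopifnot(divisor >= 1)
  if (any(weights < 0)) {
    stop("negative weight in expansion; split differential rows by the sign ",
         "of delta first", call. = FALSE)
  }
  round_half_up(weights / divisor)
}

#' Expand viabilities by read-count weight
#'
#' The central primitive of the weighted statistics: each row contributes
#' \code{round(weight / divisor)} copies of its viability to a multiset,
#' on which medians, box statistics and group comparisons are computed.
#' The divisor (default 1000) keeps multiset sizes tractable; rounding is
#' half-away-from-zero, and rows rounding to zero copies contribute
#' nothing (their number is reported). Set \code{divisor = 1} for exact
#' weighting.
#'
#' @param viability numeric vector of percent viabilities, one per row.
#' @param weights non-negative weights (normalized counts, or |delta| for
#'   differential rows split by sign).
#' @param divisor positive expansion divisor.
#' @return Numeric vector: the expanded viability multiset.
#' @export
expand_viability <- function(viability, weights, divisor = 1000) {
  stopifnot(length(viability) == length(weights))
  copies <- expansion_copies(weights, divisor)
  dropped <- sum(copies == 0L & weights > 0)
  if (dropped > 0L) {
    message(dropped, " row(s) with weight < ", divisor / 2,
            " contributed no copies to the expansion")
  }
  rep(viability, copies)
}

#' Box-plot statistics of an expanded viability multiset
#'
#' Median and hinges use the linear-interpolation quantile convention
#' (R's default, type 7). Whiskers extend to the most extreme data point
#' no further than 1.5 x IQR beyond the hinges; points beyond the
#' whiskers are outliers.
#'
#' @param values non-empty numeric vector (an expanded multiset).
#' @return List of class \code{box_stats}: \code{median}, \code{q1},
#'   \code{q3}, \code{whisker_low}, \code{whisker_high}, \code{outliers},
#'   \code{n}.
#' @export
box_stats <- function(values) {
  if (length(values) == 0L) {
    stop("box_stats on an empty multiset", call. = FALSE)
  }
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  in_lo <- values >= q[1L] - 1.5 * iqr
  in_hi <- values <= q[3L] + 1.5 * iqr
  structure(list(
    median = q[2L],
    q1 = q[1L],
    q3 = q[3L],
    whisker_low = min(values[in_lo]),
    whisker_high = max(values[in_hi]),
    outliers = sort(values[!(in_lo & in_hi)]),
    n = length(values)
  ), class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "box stats (n = %d): median %.2f, hinges [%.2f, %.2f], whiskers [%.2f, %.2f], %d outlier(s)\n",
    x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high,
    length(x$outliers)))
  invisible(x)
}

#' Compare expanded viability multisets between groups
#'
#' Kruskal-Wallis rank-sum test (with tie correction, chi-square p-value)
#' over two or more expanded multisets. When every value is identical
#' across all groups no group effect is possible; by convention H = 0 and
#' p = 1 are returned with a warning.
#'
#' @param groups named list of non-empty numeric vectors.
#' @return List with \code{H} (the Kruskal-Wallis statistic), \code{p},
#'   \code{df}.
#' @export
compare_groups <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1L) {
    warning("all values identical across groups; no group effect possible",
            call. = FALSE)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Binned viability curve
#'
#' Rows are first collapsed on (seed, RNA type), summing their weights;
#' collapsed weights are then aggregated into left-closed right-open
#' viability bins anchored at 0 (default width 1%). Bin totals conserve
#' the collapsed table's total weight exactly. Bins extend past 100% when
#' growth-enhancing seeds occur.
#'
#' @param table annotated table with \code{seed}, \code{rna_type},
#'   \code{viability} columns.
#' @param weight_column name of the weight column (a normalized count
#'   column, or \code{"delta"} magnitudes split by sign upstream).
#' @param bin_width positive bin width in percent viability.
#' @param by_type keep RNA types as separate series?
#' @return Tibble with \code{bin_left}, \code{bin_right}, \code{weight}
#'   (and \code{rna_type} when \code{by_type}).
#' @export
binned_curve <- function(table, weight_column, bin_width = 1, by_type = FALSE) {
  stopifnot(bin_width > 0)
  w <- table[[weight_column]]
  if (is.null(w)) stop("no column '", weight_column, "'", call. = FALSE)
  collapsed <- tibble::tibble(seed = table$seed,
                              rna_type = if (by_type) table$rna_type else "all",
                              viability = table$viability,
                              weight = w)
  collapsed <- dplyr::summarise(
    dplyr::group_by(collapsed, .data$seed, .data$rna_type, .data$viability),
    weight = sum(.data$weight), .groups = "drop")
  bin <- floor(collapsed$viability / bin_width)
  collapsed$bin_left <- bin * bin_width
  out <- dplyr::summarise(
    dplyr::group_by(collapsed, .data$rna_type, .data$bin_left),
    weight = sum(.data$weight), .groups = "drop")
  out$bin_right <- out$bin_left + bin_width
  out <- dplyr::arrange(out, .data$rna_type, .data$bin_left)
  cols <- c("bin_left", "bin_right", "weight")
  if (by_type) cols <- c("rna_type", cols)
  out[cols]
}

#' Binned curves of a differential table, split by sign
#'
#' Enriched rows (delta > 0) and depleted rows (delta < 0) are binned
#' separately on |delta| and returned as two series distinguished by a
#' \code{sign} column — the green/red pair of a differential viability
#' curve.
#'
#' @param diff_table a \code{\link{differential}} result.
#' @param bin_width positive bin width in percent viability.
#' @return Tibble with \code{sign} (\code{"enriched"}/\code{"depleted"}),
#'   \code{bin_left}, \code{bin_right}, \code{weight}.
#' @export
binned_curve_differential <- function(diff_table, bin_width = 1) {
  pieces <- list(enriched = diff_table[diff_table$delta > 0, ],
                 depleted = diff_table[diff_table$delta < 0, ])
  out <- lapply(names(pieces), function(sg) {
    piece <- pieces[[sg]]
    if (nrow(piece) == 0L) return(NULL)
    piece$abs_delta <- abs(piece$delta)
    curve <- binned_curve(piece, "abs_delta", bin_width)
    curve$sign <- sg
    curve[c("sign", "bin_left", "bin_right", "weight")]
  })
  dplyr::bind_rows(out)
}

#' Weighted seed nucleotide composition
#'
#' For each of the six seed positions, the relative frequency of
#' A, C, G, U over the count-weighted expansion of the table — the matrix
#' behind a sequence-logo view of the average seed. Computed without
#' literal expansion, but identical to tallying the expanded multiset:
#' each row enters with its integer copy number
#' \code{round(weight / divisor)}.
#'
#' @inheritParams binned_curve
#' @param divisor expansion divisor (see \code{\link{expand_viability}}).
#' @return 4 x 6 numeric matrix, rows A/C/G/U, columns pos1..pos6; every
#'   column sums to 1.
#' @export
seed_composition <- function(table, weight_column, divisor = 1000) {
  w <- table[[weight_column]]
  if (is.null(w)) stop("no column '", weight_column, "'", call. = FALSE)
  copies <- expansion_copies(w, divisor)
  total <- sum(copies)
  if (total == 0) {
    stop("zero total expanded weight; nothing to compose", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(table$seed, "", fixed = TRUE)),
                  ncol = 6L, byrow = TRUE)
  out <- matrix(0, nrow = 4L, ncol = 6L,
                dimnames = list(RNA_NUCS, paste0("pos", 1:6)))
  for (j in 1:6) {
    tallied <- tapply(copies, factor(chars[, j], levels = RNA_NUCS), sum)
    tallied[is.na(tallied)] <- 0
    out[, j] <- tallied / total
  }
  out
}
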