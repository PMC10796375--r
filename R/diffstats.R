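# Per-sample normalization and two-group differential selection.

#' Normalize a count table to one million reads per sample
#'
#' Each cell is scaled by 1,000,000 / (its sample's raw column total), so
#' every sample column sums to exactly one million. Columns with zero raw
#' total stay all-zero, with a warning.
#'
#' @param table raw or annotated count table.
#' @return The table with sample columns replaced by normalized values.
#' @export
normalize_counts <- function(table) {
  stopifnot(nrow(table) >= 1L)
  samples <- count_samples(table)
  for (s in samples) {
    tot <- sum(table[[s]])
    if (tot == 0) {
      warning("sample '", s, "' has zero total reads; left all-zero",
              call. = FALSE)
    } else {
      table[[s]] <- table[[s]] * (1e6 / tot)
    }
  }
  table
}

#' Select differentially RISC-loaded reads between two groups
#'
#' Per row, a two-sided equal-variance Student's t-test on normalized
#' counts between the two groups; rows with p below \code{alpha} are
#' retained with their delta read count, mean(perturbed) - mean(control).
#' Positive delta = enriched in the perturbed group, negative = depleted.
#' Rows that are identically constant across both groups carry no evidence
#' (the t statistic is undefined) and are skipped, with a count reported.
#'
#' No multiple-testing correction is applied: the selection rule is the
#' plain per-row p < alpha filter. The test name and alpha are recorded in
#' the result's attributes.
#'
#' @param norm normalized (annotated) count table.
#' @param groups named character vector mapping sample column name ->
#'   group label.
#' @param control_group,perturbed_group the two group labels to compare.
#' @param alpha significance threshold in (0,1), default 0.05.
#' @return Tibble of retained rows: annotation columns plus
#'   \code{mean_control}, \code{mean_perturbed}, \code{delta}, \code{p}.
#' @export
differential <- function(norm, groups, control_group, perturbed_group,
                         alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ctrl <- names(groups)[groups == control_group]
  pert <- names(groups)[groups == perturbed_group]
  missing_cols <- setdiff(c(ctrl, pert), names(norm))
  if (length(missing_cols)) {
    stop("group sample(s) not in table: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n1 <- length(ctrl)
  n2 <- length(pert)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs >= 2 samples: within-group variance is required ",
         "for the t-test", call. = FALSE)
  }
  x <- as.matrix(norm[ctrl])  # control
  y <- as.matrix(norm[pert])  # perturbed
  mx <- rowMeans(x)
  my <- rowMeans(y)
  ssx <- rowSums((x - mx)^2)
  ssy <- rowSums((y - my)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ssx + ssy) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- my - mx
  p <- ifelse(se > 0,
              2 * stats::pt(-abs(delta / se), df),
              ifelse(delta == 0, NA_real_, 0))
  skipped <- is.na(p)
  if (any(skipped)) {
    message(sum(skipped), " row(s) identically constant in both groups skipped")
  }
  keep <- !skipped & p < alpha
  out <- norm[keep, setdiff(names(norm), c(ctrl, pert))]
  out$mean_control <- mx[keep]
  out$mean_perturbed <- my[keep]
  out$delta <- delta[keep]
  out$p <- p[keep]
  attr(out, "test") <- "two-sided equal-variance Student's t-test"
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- sum(!skipped)
  attr(out, "groups") <- list(control = ctrl, perturbed = pert)
  out
}
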