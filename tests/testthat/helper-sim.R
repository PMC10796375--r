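# Shared fixtures and independent oracles, all built in code.

.fixture_cache <- new.env(parent = emptyenv())

# one synthetic viability lookup shared across tests (generation is
# deterministic; caching only saves time)
test_viab <- function() {
  if (is.null(.fixture_cache$viab)) {
    .fixture_cache$viab <- gen_viability_table(11)
  }
  .fixture_cache$viab
}

std_groups <- function(k = 3L) {
  setNames(rep(c("control", "perturbed"), each = k),
           c(paste0("control_", seq_len(k)), paste0("perturbed_", seq_len(k))))
}

# a random annotated-style table: seed, rna_type, viability, weight
rand_weighted_table <- function(n, viab = test_viab()) {
  idx <- sample(nrow(viab), n, replace = TRUE)
  tibble::tibble(
    seed = viab$seed[idx],
    rna_type = sample(c("miRNA", "RNAworld", "unknown"), n, replace = TRUE),
    viability = viab$human_avg[idx],
    weight = stats::rlnorm(n, meanlog = 6, sdlog = 1.5)
  )
}

# literal row-replication oracle for the expansion
literal_expand <- function(viability, weights, divisor) {
  out <- numeric(0)
  for (i in seq_along(weights)) {
    k <- floor(weights[i] / divisor + 0.5)
    if (k >= 1) out <- c(out, rep(viability[i], k))
  }
  out
}

# literal-expansion tally oracle for the composition matrix
literal_composition <- function(tbl, weight_col, divisor) {
  seeds_expanded <- character(0)
  for (i in seq_len(nrow(tbl))) {
    k <- floor(tbl[[weight_col]][i] / divisor + 0.5)
    if (k >= 1) seeds_expanded <- c(seeds_expanded, rep(tbl$seed[i], k))
  }
  mat <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "U"),
                                         paste0("pos", 1:6)))
  for (j in 1:6) {
    ch <- substr(seeds_expanded, j, j)
    for (nuc in rownames(mat)) mat[nuc, j] <- sum(ch == nuc)
  }
  mat / length(seeds_expanded)
}

# brute-force collapse-then-bin oracle
brute_binned <- function(tbl, weight_col, bin_width) {
  key <- paste(tbl$seed, tbl$rna_type, sep = "|")
  agg <- tapply(tbl[[weight_col]], key, sum)
  viab_by_key <- tapply(tbl$viability, key, function(v) v[1])
  bins <- floor(viab_by_key / bin_width) * bin_width
  totals <- tapply(as.numeric(agg), bins, sum)
  tibble::tibble(bin_left = as.numeric(names(totals)),
                 weight = as.numeric(totals))[order(as.numeric(names(totals))), ]
}

# direct implementation of the box/whisker figure-legend rule
brute_box <- function(values) {
  q1 <- unname(quantile(values, 0.25, type = 7))
  q3 <- unname(quantile(values, 0.75, type = 7))
  iqr <- q3 - q1
  inside <- values >= q1 - 1.5 * iqr & values <= q3 + 1.5 * iqr
  list(q1 = q1, q3 = q3,
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}
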