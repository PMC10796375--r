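test_that("expand_viability replicates viabilities by rounded weight", {
  expect_equal(expand_viability(40, 3000, 1000), c(40, 40, 40))
  # rounding is half-away-from-zero
  expect_equal(expand_viability(40, 1500, 1000), c(40, 40))
  expect_message(ev <- expand_viability(40, 400, 1000), "no copies")
  expect_length(ev, 0L)
  expect_error(expand_viability(40, -5, 1000), "negative weight")
})

test_that("expansion matches the literal row-replication oracle", {
  set.seed(61)
  for (rep_i in 1:10) {
    tbl <- rand_weighted_table(100)
    for (divisor in c(1, 250, 1000)) {
      got <- suppressMessages(
        expand_viability(tbl$viability, tbl$weight, divisor))
      expect_equal(sort(got),
                   sort(literal_expand(tbl$viability, tbl$weight, divisor)))
    }
  }
})

test_that("box_stats follows the quartile and 1.5*IQR whisker rule", {
  b <- box_stats(c(10, 20, 30))
  expect_equal(b$median, 20)
  expect_equal(b$q1, 15)
  expect_equal(b$q3, 25)

  const <- box_stats(rep(50, 100))
  expect_equal(const$median, 50)
  expect_equal(const$q1, 50)
  expect_equal(const$q3, 50)
  expect_length(const$outliers, 0L)

  expect_error(box_stats(numeric(0)), "empty")

  set.seed(62)
  for (rep_i in 1:20) {
    v <- rlnorm(500, 4, 0.6)
    b <- box_stats(v)
    expect_true(b$q1 <= b$median && b$median <= b$q3)
    # median from direct order statistics
    s <- sort(v)
    expect_equal(b$median, (s[250] + s[251]) / 2)
    o <- brute_box(v)
    expect_equal(b$whisker_low, o$whisker_low)
    expect_equal(b$whisker_high, o$whisker_high)
    expect_equal(b$outliers, o$outliers)
  }
})

test_that("compare_groups is the tie-corrected Kruskal-Wallis rank-sum test", {
  # two identical multisets: no group effect possible
  same <- compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$p, 1)
  expect_equal(same$H, 0)
  # fully constant data takes the warning path
  expect_warning(const <- compare_groups(list(a = rep(5, 4), b = rep(5, 3))),
                 "identical")
  expect_equal(const$p, 1)

  # hand-computed rank sums for n = 6, no ties: H = 12/(6*7)*(12+75) - 21
  kw <- compare_groups(list(a = c(1, 2, 3), b = c(101, 102, 103)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-10)
  expect_true(kw$p < 0.06)

  # invariant to group input order
  set.seed(63)
  g1 <- rlnorm(40, 4, 1)
  g2 <- rlnorm(30, 4.2, 1)
  g3 <- rlnorm(20, 3.8, 1)
  a <- compare_groups(list(g1 = g1, g2 = g2, g3 = g3))
  b <- compare_groups(list(g3 = g3, g1 = g1, g2 = g2))
  expect_equal(a$H, b$H)
  expect_equal(a$p, b$p)
  # and identical to kruskal.test called directly
  kt <- kruskal.test(list(g1, g2, g3))
  expect_equal(a$H, unname(kt$statistic))
  expect_equal(a$p, kt$p.value)
})

test_that("binned_curve collapses on (seed, rna_type) then bins half-open", {
  tbl <- tibble::tibble(seed = c("GGCAGU", "GGCAGU", "AAAAAA"),
                        rna_type = c("miRNA", "miRNA", "miRNA"),
                        viability = c(19.2, 19.2, 19.9),
                        weight = c(100, 200, 50))
  cur <- binned_curve(tbl, "weight", bin_width = 1)
  expect_identical(nrow(cur), 1L)  # both seeds fall in [19, 20)
  expect_equal(cur$bin_left, 19)
  expect_equal(cur$bin_right, 20)
  expect_equal(cur$weight, 350)

  # same seed, different rna_type stays separate when requested
  tbl$rna_type <- c("miRNA", "RNAworld", "miRNA")
  cur2 <- binned_curve(tbl, "weight", 1, by_type = TRUE)
  expect_identical(nrow(cur2), 2L)
  expect_equal(sum(cur2$weight), 350)
})

test_that("binned_curve equals the brute-force oracle and conserves weight", {
  set.seed(64)
  for (rep_i in 1:10) {
    tbl <- rand_weighted_table(300)
    for (bw in c(1, 2.5)) {
      cur <- binned_curve(tbl, "weight", bw)
      oracle <- brute_binned(tbl, "weight", bw)
      expect_equal(cur$bin_left, oracle$bin_left)
      expect_equal(cur$weight, oracle$weight)
      expect_equal(sum(cur$weight), sum(tbl$weight))
    }
  }
})

test_that("seed_composition matches literal expansion tallies", {
  viab <- test_viab()
  one <- tibble::tibble(seed = "GGGGGC", rna_type = "miRNA",
                        viability = 10, weight = 7000)
  m <- seed_composition(one, "weight", 1000)
  expect_equal(unname(m["G", 1:5]), rep(1, 5))
  expect_equal(unname(m["C", 6]), 1)
  expect_equal(colSums(m), setNames(rep(1, 6), paste0("pos", 1:6)))

  two <- tibble::tibble(seed = c("AAAAAA", "UUUUUU"), rna_type = "miRNA",
                        viability = c(100, 100), weight = c(5000, 5000))
  m2 <- seed_composition(two, "weight", 1000)
  expect_equal(unname(m2["A", ]), rep(0.5, 6))
  expect_equal(unname(m2["U", ]), rep(0.5, 6))

  set.seed(65)
  for (rep_i in 1:10) {
    tbl <- rand_weighted_table(50)
    m <- seed_composition(tbl, "weight", 1000)
    expect_equal(m, literal_composition(tbl, "weight", 1000))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_error(seed_composition(
    tibble::tibble(seed = "AAAAAA", viability = 1, weight = 100),
    "weight", 1000), "zero total")
})

test_that("divisor-rescaled weights reproduce divisor-1 statistics", {
  set.seed(66)
  tbl <- rand_weighted_table(200)
  tbl$weight_int <- floor(tbl$weight / 100 + 0.5)  # integer copies
  tbl$weight_scaled <- tbl$weight_int * 1000
  ev1 <- expand_viability(tbl$viability, tbl$weight_int, 1)
  ev2 <- suppressMessages(
    expand_viability(tbl$viability, tbl$weight_scaled, 1000))
  expect_equal(sort(ev1), sort(ev2))
  keep <- tbl$weight_int > 0
  if (any(keep)) {
    expect_equal(seed_composition(tbl[keep, ], "weight_int", 1),
                 seed_composition(tbl[keep, ], "weight_scaled", 1000))
  }
})

test_that("adding low-viability weight never raises the median", {
  set.seed(67)
  for (rep_i in 1:10) {
    tbl <- rand_weighted_table(150)
    ev <- suppressMessages(expand_viability(tbl$viability, tbl$weight, 1000))
    med <- median(ev)
    low <- tbl$viability < med
    boosted <- tbl$weight
    boosted[low] <- boosted[low] + 5000
    ev2 <- suppressMessages(expand_viability(tbl$viability, boosted, 1000))
    expect_true(median(ev2) <= med)
  }
})
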