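test_that("gen_viability_table is complete, toxicity-structured, deterministic", {
  viab <- test_viab()
  expect_identical(nrow(viab), 4096L)
  expect_setequal(viab$seed, all_seeds())
  vals <- as.matrix(tibble::as_tibble(viab)[c(paste0("human", 1:3),
                                              paste0("mouse", 1:3))])
  expect_true(all(vals >= 0))
  # G-rich seeds sit at the toxic end by construction
  base <- sixmer:::seed_base_viability
  expect_true(base("GGGGGG") < base("AAAAAA"))
  set.seed(71)
  others <- sample(all_seeds(), 50)
  expect_true(all(base("GGGGGG") <= base(others)))
  expect_true(all(base(others) <= base("AAAAAA")))
  # same seed -> byte-identical CSV
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_viability_table(gen_viability_table(123), p1)
  write_viability_table(gen_viability_table(123), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("sim_config validates its domain", {
  expect_error(sim_config(samples_per_group = 1), ">= 2")
  expect_error(sim_config(shift = 1.5))
  expect_error(sim_config(fraction_mirna = 0.8, fraction_rnaworld = 0.3))
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
})

test_that("gen_counts embeds seeds at 2-7 and encodes the shift in truth", {
  viab <- test_viab()
  cfg <- sim_config(rng_seed = 72, n_rows = 150, shift = 0.8, depth = 5e4)
  sim <- gen_counts(cfg, viab)
  expect_identical(nrow(sim$table), 150L)
  expect_identical(sort(sim$table$sequence), sort(sim$truth$sequence))
  i <- match(sim$table$sequence, sim$truth$sequence)
  expect_identical(substr(sim$table$sequence, 2, 7), sim$truth$seed[i])
  # expected (truth-level) weighted medians respect the shift direction
  wmed <- function(v, w) median(rep(v, round(w)))
  expect_lt(wmed(sim$truth$viability, sim$truth$mean_perturbed),
            wmed(sim$truth$viability, sim$truth$mean_control))
  # same config twice -> identical draw
  sim2 <- gen_counts(cfg, viab)
  expect_identical(sim, sim2)
  # expected depth is honored
  expect_equal(sum(sim$truth$mean_control), cfg$depth)
})

test_that("gen_references cover planted rows and drive artificial removal", {
  viab <- test_viab()
  cfg <- sim_config(rng_seed = 73, n_rows = 200, shift = 0, depth = 5e4,
                    fraction_artificial = 0.1)
  sim <- gen_counts(cfg, viab)
  refs <- gen_references(sim$truth, 73)
  # every simulated miRNA row is a reference, verbatim
  mir_rows <- sim$truth$sequence[sim$truth$rna_type == "miRNA"]
  expect_true(all(mir_rows %in% refs$miRNA$sequences))
  # disjointness: no miRNA reference inside an artificial decoy
  for (m in refs$miRNA$sequences) {
    expect_false(any(grepl(m, refs$artificial$sequences, fixed = TRUE)))
  }
  # the rows removed by annotation are exactly the planted artificial rows
  ann <- suppressMessages(annotate_table(sim$table, refs, "human", viab))
  removed <- setdiff(sim$table$sequence, ann$sequence)
  planted <- sim$truth$sequence[sim$truth$rna_type == "artificial"]
  expect_setequal(removed, planted)
  # surviving rows carry their true type
  i <- match(ann$sequence, sim$truth$sequence)
  expect_identical(ann$rna_type, sim$truth$rna_type[i])
})

test_that("gen_fastq inverts preprocessing exactly", {
  viab <- test_viab()
  cfg <- sim_config(rng_seed = 74, n_rows = 80, shift = 0.4, depth = 2e4)
  sim <- gen_counts(cfg, viab)
  tab <- suppressMessages(filter_rare(sim$table, 6))
  adapter <- "UGGAAUUCUCGGGUGCCAAGG"
  dir <- withr::local_tempdir()
  paths <- gen_fastq(tab, adapter, dir, 74)
  # record counts equal column sums
  for (s in names(paths)) {
    expect_identical(length(readLines(paths[[s]])) %/% 4L,
                     as.integer(sum(tab[[s]])))
  }
  back <- suppressMessages(fastq_to_counts(paths, adapter, 4, 6))
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("gen_fastq handles an empty table", {
  tbl <- tibble::tibble(sequence = character(0), s1 = integer(0))
  dir <- withr::local_tempdir()
  paths <- gen_fastq(tbl, "UGGAAUUC", dir, 1)
  expect_true(file.exists(paths[["s1"]]))
  expect_identical(length(readLines(paths[["s1"]])), 0L)
})

test_that("median-viability response is monotone in the injected shift", {
  viab <- test_viab()
  diffs <- vapply(c(0, 0.4, 0.8), function(sh) {
    mean(vapply(1:8, function(r) {
      cfg <- sim_config(rng_seed = 7500 + r, n_rows = 200, shift = sh,
                        depth = 1e5)
      sim <- gen_counts(cfg, viab)
      norm <- normalize_counts(sim$table)
      v <- seed_viability(extract_seed(norm$sequence), "human", viab)
      mc <- rowMeans(norm[paste0("control_", 1:3)])
      mp <- rowMeans(norm[paste0("perturbed_", 1:3)])
      median(suppressMessages(expand_viability(v, mp))) -
        median(suppressMessages(expand_viability(v, mc)))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(diffs[1] > diffs[2] && diffs[2] > diffs[3])
})
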