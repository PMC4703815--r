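test_that("generation is deterministic given the seed", {
  a <- simulate_assemblies(small_sim_config(seed = 5))
  b <- simulate_assemblies(small_sim_config(seed = 5))
  for (s in a$samples$samples) {
    expect_identical(as.character(a$samples$sequences[[s]]),
                     as.character(b$samples$sequences[[s]]))
  }
  expect_identical(a$truth, b$truth)
  expect_identical(a$truth_samples, b$truth_samples)
  c2 <- simulate_assemblies(small_sim_config(seed = 6))
  expect_false(identical(as.character(a$samples$sequences$REF),
                         as.character(c2$samples$sequences$REF)))
})

test_that("planted tracts sit at the recorded coordinates with the planted counts", {
  sim <- simulate_assemblies(small_sim_config(seed = 8, noiseless = TRUE))
  for (s in sim$samples$samples) {
    seq <- unname(as.character(sim$samples$sequences[[s]]))
    ts <- dplyr::left_join(
      sim$truth_samples[sim$truth_samples$sample == s, ],
      sim$truth, by = "truth_id")
    for (i in seq_len(nrow(ts))) {
      expect_equal(
        substr(seq, ts$tract_start[i] + 1,
               ts$tract_start[i] + ts$repeats[i] * ts$motif_len[i]),
        strrep(ts$motif[i], ts$repeats[i]))
    }
  }
})

test_that("the polymorphic flag reflects distinct counts among surviving samples", {
  sim <- simulate_assemblies(small_sim_config(seed = 9))
  counts <- sim$truth_samples[!is.na(sim$truth_samples$repeats), ]
  k <- tapply(counts$repeats, counts$truth_id, function(x) length(unique(x)))
  expect_equal(sim$truth$polymorphic,
               as.vector(k[sim$truth$truth_id] > 1))
})

test_that("forced offsets and total dropout behave as configured", {
  # offsets forced to +2: every sample repeat count = reference + 2
  sim <- simulate_assemblies(small_sim_config(
    seed = 10, noiseless = TRUE, n_samples = 2L, n_loci = 4L,
    frac_polymorphic = 1, offset_range = c(2L, 2L)))
  merged <- dplyr::left_join(
    sim$truth_samples[sim$truth_samples$sample == "S1", ],
    sim$truth, by = "truth_id")
  expect_equal(merged$repeats, merged$ref_repeats + 2L)
  expect_true(all(sim$truth$polymorphic))

  # dropout probability 1: everything dropped, MR = 1, nothing passes
  sim2 <- simulate_assemblies(small_sim_config(
    seed = 11, dropout_prob = 1, n_loci = 4L))
  expect_true(all(sim2$truth_samples$dropped[
    sim2$truth_samples$sample != "REF"]))
  res <- polyssr_run(sim2$samples)
  expect_equal(nrow(res$candidates), 0L)
  expect_false(any(res$loci$passes))
  # the planted loci themselves are fully missing
  ev <- evaluate_recovery(res, sim2)
  expect_false(any(ev$per_locus$detected))
})

test_that("paralog duplication forces an ambiguous call", {
  sim <- simulate_assemblies(small_sim_config(
    seed = 12, noiseless = TRUE, n_samples = 3L, n_loci = 4L,
    paralog_prob = 1))
  res <- polyssr_run(sim$samples)
  expect_true(all(res$observations$status == "AMBIGUOUS"))
  expect_equal(nrow(res$candidates), 0L)   # MR = 1 everywhere
})

test_that("the fixed scenario carries the published allele series", {
  sc <- scenario_cpssr4933()
  expect_equal(sc$truth$motif, "CCACGG")
  expect_equal(sc$truth$ref_repeats, 5L)
  expect_setequal(sc$truth_samples$repeats, c(5L, 4L, 4L, 4L, 3L, 1L))
  # the two substitutions leave exactly one continuous copy
  s5 <- as.character(sc$samples$sequences$S5)
  tract <- substr(s5, 2001, 2030)
  expect_equal(oracle_tandem_run(tract, "CCACGG"), 1L)
  # byte-identical regeneration
  sc2 <- scenario_cpssr4933()
  expect_identical(as.character(sc$samples$sequences$S5),
                   as.character(sc2$samples$sequences$S5))
})

test_that("write_sim emits FASTAs that round-trip plus a readable truth table", {
  sim <- simulate_assemblies(small_sim_config(seed = 13, n_loci = 3L))
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  back <- read_fasta(file.path(dir, "REF.fasta"), "REF")
  expect_equal(back$residues, as.character(sim$samples$sequences$REF),
               ignore_attr = TRUE)
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(truth), nrow(sim$truth_samples))
})

test_that("impossible placement is rejected", {
  expect_error(
    simulate_assemblies(sim_config(seed = 1, seq_length = 5000,
                                   n_loci = 50)),
    "cannot place")
})
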