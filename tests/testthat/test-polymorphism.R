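test_that("genotyping counts motif copies in the elongated hit region", {
  withr::local_seed(41)
  motif <- "CCACGG"
  loci <- tibble::tibble(locus_id = "L1", motif = motif)
  left <- paste0(random_dna(1, 198), "TA")   # junction cannot extend the array
  right <- paste0("AT", random_dna(1, 198))
  for (n in c(4L, 3L)) {
    target <- paste0(left, strrep(motif, n), right)
    best <- tibble::tibble(locus_id = "L1", sample = "s1", seq_id = "t",
                           start = 100L, end = nchar(target) - 100L,
                           strand = "+", status = "HIT")
    obs <- genotype_hits(best, loci, setNames(target, "t"), elongation = 50)
    expect_equal(obs$status, "FOUND")
    expect_equal(obs$repeats, n)
  }
})

test_that("a substitution-broken array is genotyped at its longest intact run", {
  withr::local_seed(42)
  motif <- "CCACGG"
  tract <- strrep(motif, 5)
  substr(tract, 7, 7) <- "T"     # first base of copy 2
  substr(tract, 19, 19) <- "T"   # first base of copy 4
  target <- paste0(random_dna(1, 150), "TA", tract, "AT", random_dna(1, 150))
  best <- tibble::tibble(locus_id = "L1", sample = "s1", seq_id = "t",
                         start = 50L, end = nchar(target) - 50L,
                         strand = "+", status = "HIT")
  obs <- genotype_hits(best, tibble::tibble(locus_id = "L1", motif = motif),
                       setNames(target, "t"), elongation = 20)
  expect_equal(obs$status, "FOUND")
  expect_equal(obs$repeats, 1L)
  expect_equal(obs$repeats, oracle_tandem_run(tract, motif))
})

test_that("a region without any motif copy is MISSING", {
  target <- strrep("T", 400)
  best <- tibble::tibble(locus_id = "L1", sample = "s1", seq_id = "t",
                         start = 100L, end = 300L, strand = "+",
                         status = "HIT")
  obs <- genotype_hits(best, tibble::tibble(locus_id = "L1", motif = "ACG"),
                       setNames(target, "t"))
  expect_equal(obs$status, "MISSING")
  expect_true(is.na(obs$repeats))
})

test_that("minus-strand hits are genotyped on the oriented region", {
  withr::local_seed(43)
  motif <- "ACC"
  plus <- paste0(random_dna(1, 100), strrep(motif, 6), random_dna(1, 100))
  target <- oracle_revcomp(plus)
  n <- nchar(target)
  best <- tibble::tibble(locus_id = "L1", sample = "s1", seq_id = "t",
                         start = 0L, end = n, strand = "-", status = "HIT")
  obs <- genotype_hits(best, tibble::tibble(locus_id = "L1", motif = motif),
                       setNames(target, "t"), elongation = 0)
  expect_equal(obs$status, "FOUND")
  expect_gte(obs$repeats, 6L)
})

test_that("score_locus reproduces the direct SD and MR formulas", {
  # population SD over {5,4,4,4,3}, one missing sample of five
  sc <- score_locus(status = c("FOUND", "FOUND", "FOUND", "FOUND", "MISSING"),
                    repeats = c(4L, 4L, 4L, 3L, NA),
                    ref_repeats = 5L)
  expect_equal(sc$sd, 0.6325, tolerance = 1e-4)
  expect_equal(sc$mr, 0.2)
  expect_true(sc$passes)

  all_equal <- score_locus(rep("FOUND", 3), c(6L, 6L, 6L), 6L)
  expect_equal(all_equal$sd, 0)
  expect_false(all_equal$passes)

  mostly_missing <- score_locus(
    c("FOUND", "FOUND", "MISSING", "MISSING", "MISSING"),
    c(4L, 5L, NA, NA, NA), 5L)
  expect_equal(mostly_missing$mr, 0.6)
  expect_false(mostly_missing$passes)

  none <- score_locus(rep("MISSING", 4), rep(NA_integer_, 4), 5L)
  expect_equal(none$mr, 1.0)
  expect_false(none$passes)

  expect_error(score_locus(character(0), integer(0), 5L), "at least one")
})

test_that("ambiguous samples count toward MR and are excluded from SD", {
  sc <- score_locus(c("FOUND", "AMBIGUOUS", "FOUND"), c(4L, NA, 6L), 5L)
  expect_equal(sc$mr, 1 / 3)
  expect_equal(sc$sd, sqrt(mean((c(5, 4, 6) - 5)^2)))
  expect_equal(sc$n_ambiguous, 1L)
})

test_that("SD is permutation-invariant and zero iff all counts equal", {
  withr::local_seed(44)
  for (i in 1:20) {
    reps <- sample(3:9, 5, replace = TRUE)
    st <- rep("FOUND", 5)
    a <- score_locus(st, reps, 6L)
    perm <- sample(5)
    b <- score_locus(st[perm], reps[perm], 6L)
    expect_equal(a$sd, b$sd)
    expect_equal(a$sd == 0, all(c(reps, 6L) == c(reps, 6L)[1]))
    if (a$passes) expect_gte(dplyr::n_distinct(c(reps, 6L)), 2L)
  }
})
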