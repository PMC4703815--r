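make_flanked_query <- function(q, locus_id = "Q1") {
  tibble::tibble(locus_id = locus_id, query = q)
}

test_that("extract_flanked slices and clips flanks correctly", {
  withr::local_seed(31)
  s <- random_dna(1, 1000)
  loci <- tibble::tibble(locus_id = "L1", seq_id = "x", start = 100L,
                         end = 112L)
  fl <- extract_flanked(loci, setNames(s, "x"), flank_length = 100)
  expect_equal(fl$upstream, substr(s, 1, 100))
  expect_equal(fl$downstream, substr(s, 113, 212))
  expect_false(fl$trunc_up || fl$trunc_down)
  expect_equal(nchar(fl$query),
               nchar(fl$upstream) + (fl$end - fl$start) + nchar(fl$downstream))
  # query is a verbatim substring of the reference
  expect_true(grepl(fl$query, s, fixed = TRUE))

  loci2 <- tibble::tibble(locus_id = "L2", seq_id = "x", start = 5L,
                          end = 17L)
  expect_message(
    fl2 <- extract_flanked(loci2, setNames(s, "x"), flank_length = 100),
    "truncated")
  expect_equal(nchar(fl2$upstream), 5L)
  expect_true(fl2$trunc_up)
})

test_that("verbatim and reverse-complement copies are found with identity 1", {
  withr::local_seed(32)
  q <- random_dna(1, 300)
  target <- paste0(random_dna(1, 500), q, random_dna(1, 500))
  hits <- search_sample(make_flanked_query(q), c(t1 = target), "s1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 500L)
  expect_equal(hits$end, 800L)

  rc_target <- oracle_revcomp(target)
  hits2 <- search_sample(make_flanked_query(q), c(t1 = rc_target), "s1")
  expect_equal(nrow(hits2), 1L)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$identity, 1.0)
  # coordinates mirrored
  expect_equal(hits2$start, nchar(target) - 800L)
  expect_equal(hits2$end, nchar(target) - 500L)
})

test_that("a copy with three substitutions scores as the oracle predicts", {
  withr::local_seed(33)
  q <- random_dna(1, 300)
  qm <- mutate_dna(q, n_sub = 3)
  target <- paste0(random_dna(1, 400), qm, random_dna(1, 400))
  hits <- search_sample(make_flanked_query(q), c(t1 = target), "s1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 297 / 300, tolerance = 1e-6)
  expect_equal(hits$coverage, 1.0)
  o <- oracle_local_alignment(q, target)
  expect_lte(abs(hits$identity - o$identity), 0.01)
})

test_that("an unrelated sample yields no hits at default thresholds", {
  withr::local_seed(34)
  q <- random_dna(1, 300)
  target <- random_dna(1, 2000)
  hits <- search_sample(make_flanked_query(q), c(t1 = target), "s1")
  expect_equal(nrow(hits), 0L)
})

test_that("search results do not depend on target iteration order", {
  withr::local_seed(35)
  q <- random_dna(1, 250)
  t1 <- paste0(random_dna(1, 300), q, random_dna(1, 300))
  t2 <- paste0(random_dna(1, 200), mutate_dna(q, n_sub = 2),
               random_dna(1, 400))
  h12 <- search_sample(make_flanked_query(q), c(a = t1, b = t2), "s1")
  h21 <- search_sample(make_flanked_query(q), c(b = t2, a = t1), "s1")
  expect_equal(dplyr::arrange(h12, seq_id),
               dplyr::arrange(h21, seq_id))
  expect_equal(nrow(h12), 2L)
})

test_that("queries shorter than the seed length are skipped with a warning", {
  expect_warning(
    hits <- search_sample(make_flanked_query("ACGTACG"), c(t = "ACGTACGT"),
                          "s1"),
    "shorter than seed")
  expect_equal(nrow(hits), 0L)
})

test_that("best_hits applies score, tie-breaks and the ambiguity rule", {
  base <- tibble::tibble(locus_id = "L1", sample = "s1", seq_id = "t",
                         strand = "+", identity = 0.99, coverage = 1)
  one <- dplyr::mutate(base, start = 10L, end = 100L, score = 200)
  expect_equal(best_hits(one)$status, "HIT")

  two <- dplyr::bind_rows(
    dplyr::mutate(base, start = 10L, end = 100L, score = 200),
    dplyr::mutate(base, start = 500L, end = 590L, score = 150))
  b <- best_hits(two, ambiguity_ratio = 0.9)
  expect_equal(b$status, "HIT")        # 150 < 0.9 * 200
  expect_equal(b$start, 10L)

  close2 <- dplyr::bind_rows(
    dplyr::mutate(base, start = 10L, end = 100L, score = 200),
    dplyr::mutate(base, start = 500L, end = 590L, score = 190))
  expect_equal(best_hits(close2, 0.9)$status, "AMBIGUOUS")  # 190 >= 180

  # ties: higher identity, then leftmost, then + strand
  tie <- dplyr::bind_rows(
    dplyr::mutate(base, start = 500L, end = 590L, score = 200,
                  identity = 0.97),
    dplyr::mutate(base, start = 10L, end = 100L, score = 200,
                  identity = 0.99))
  expect_equal(best_hits(tie)$start, 10L)
})

test_that("the tabular-hit adapter converts coordinates and filters", {
  fl <- tibble::tibble(locus_id = "L1", query = strrep("A", 200))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "L1\tchr9\t99.0\t200\t2\t0\t1\t200\t1001\t1200\t1e-50\t360",
    "L1\tchr9\t90.0\t200\t20\t0\t1\t200\t5001\t5200\t1e-20\t200",
    "L1\tchr9\t99.5\t200\t1\t0\t1\t200\t8200\t8001\t1e-60\t370"), tf)
  hits <- read_tabular_hits(tf, fl, "s2")
  expect_equal(nrow(hits), 2L)              # the 90% hit fails MI
  expect_setequal(hits$strand, c("+", "-"))
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 1000L)
  expect_equal(plus$end, 1200L)
})
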