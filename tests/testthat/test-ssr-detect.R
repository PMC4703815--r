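test_that("find_ssrs reports constructed arrays with correct motif and count", {
  withr::local_seed(101)
  pad1 <- paste0(random_dna(1, 48), "CC")  # cannot extend an AT array
  pad2 <- paste0("CC", random_dna(1, 48))
  s <- paste0(pad1, strrep("AT", 7), pad2)
  loci <- find_ssrs(setNames(s, "x"))
  at <- loci[loci$motif_class == "AT/AT", ]
  expect_equal(nrow(at), 1L)
  expect_equal(at$repeats, 7L)
  expect_equal(at$end - at$start, at$repeats * nchar(at$motif))

  hexa <- find_ssrs(c(x = "CCACGGCCACGGCCACGGCCACGGCCACGG"))
  expect_equal(hexa$motif, "CCACGG")
  expect_equal(hexa$repeats, 5L)
})

test_that("mononucleotide runs and sub-threshold arrays are not reported", {
  expect_equal(nrow(find_ssrs(c(x = strrep("A", 20)))), 0L)
  expect_equal(nrow(find_ssrs(c(x = strrep("AC", 5)))), 0L)  # t2 = 6
  expect_equal(nrow(find_ssrs(c(x = strrep("AC", 5)),
                              repeat_thresholds(di = 5L))), 1L)
})

test_that("arrays are reported at the primitive period only", {
  loci <- find_ssrs(c(x = strrep("AT", 6)))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$repeats, 6L)
  # never additionally as ATAT x3
  expect_false(any(loci$motif == "ATAT"))
})

test_that("N breaks arrays and never appears inside a locus", {
  s <- paste0(strrep("AG", 4), "N", strrep("AG", 6))
  loci <- find_ssrs(c(x = s))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$repeats, 6L)
  expect_equal(loci$start, 9L)
})

test_that("detector agrees with the brute-force enumerator on random sequences", {
  withr::local_seed(202)
  for (i in 1:60) {
    s <- random_dna(1, 400)
    got <- find_ssrs(setNames(s, "x"))
    want <- oracle_find_ssrs(s)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$motif, want$motif)
      expect_equal(got$repeats, want$repeats)
    }
  }
})

test_that("same-class loci on one sequence do not overlap (random sequences)", {
  withr::local_seed(303)
  # enrich with planted arrays so loci actually occur
  for (i in 1:25) {
    # two arrays of the same class (AG/CT) plus a third class nearby
    s <- paste0(random_dna(1, 100), strrep("AG", 8), random_dna(1, 60),
                strrep("CT", 7), random_dna(1, 40), strrep("AGG", 6),
                random_dna(1, 100))
    loci <- find_ssrs(setNames(s, "x"), repeat_thresholds(di = 5L, tri = 4L))
    expect_gte(nrow(loci), 3L)
    cmb <- utils::combn(seq_len(nrow(loci)), 2)
    worst <- -1L
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      if (loci$motif_class[a] != loci$motif_class[b]) next
      worst <- max(worst, min(loci$end[a], loci$end[b]) -
                     max(loci$start[a], loci$start[b]))
    }
    expect_lte(worst, 0)
  }
})

test_that("canonical motif class merges reverse complements, not rotations", {
  expect_equal(canonical_motif_class(c("GA", "CT", "TA", "GGT")),
               c("GA/TC", "AG/CT", "TA/TA", "ACC/GGT"))
  expect_error(canonical_motif_class("AN"), "undefined|ACGT")
  # class must be invariant under reverse complement (checked exhaustively
  # in the acceptance suite; spot-check the property here)
  withr::local_seed(11)
  motifs <- replicate(50, paste(sample(c("A", "C", "G", "T"),
                                       sample(2:6, 1), replace = TRUE),
                                collapse = ""))
  expect_equal(canonical_motif_class(motifs),
               canonical_motif_class(oracle_revcomp(motifs)))
})

test_that("count_tandem_run matches the exhaustive rotation scan", {
  # rotation CACGGC runs three full copies at phase 0 of this string
  s <- "CACGGCCACGGCCACGGC"
  expect_equal(oracle_tandem_run(s, "CCACGG"), 3L)
  expect_equal(count_tandem_run(s, "CCACGG", phase_tolerant = TRUE), 3L)
  # phase-intolerant counting sees the CCACGG frame only
  expect_equal(count_tandem_run(s, "CCACGG", phase_tolerant = FALSE), 2L)
  expect_equal(count_tandem_run("TTTTTTTT", "ACG"), 0L)
  expect_equal(count_tandem_run(strrep("ACGT", 5), "ACGT"), 5L)

  # a partial leading copy must not swallow the head of the true run
  s2 <- paste0("GCAGTG", strrep("TGT", 7), "CAT")
  expect_equal(count_tandem_run(s2, "TGT"), 7L)
  expect_equal(oracle_tandem_run(s2, "TGT"), 7L)

  withr::local_seed(404)
  for (i in 1:40) {
    motif <- random_primitive_motif(sample(2:4, 1))
    s <- paste0(random_dna(1, 30), strrep(motif, sample(1:6, 1)),
                random_dna(1, 30))
    expect_equal(count_tandem_run(s, motif), oracle_tandem_run(s, motif))
  }
})

test_that("planted copies are never undercounted", {
  withr::local_seed(505)
  for (i in 1:30) {
    motif <- random_primitive_motif(sample(2:6, 1))
    n <- sample(2:8, 1)
    s <- paste0(random_dna(1, 20), strrep(motif, n), random_dna(1, 20))
    expect_gte(count_tandem_run(s, motif), n)
  }
})
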