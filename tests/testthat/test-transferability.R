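# Build a minimal flanked locus + observations fixture where every string is
# controlled, so expected similarities can be computed by hand.
make_fixture <- function(sample_flank_edits = list(), n_samples = 5,
                         flank_len = 100, motif = "AG", ref_copies = 6,
                         sample_copies = 5) {
  withr::local_seed(61)
  up <- paste0(random_dna(1, flank_len - 2), "CC")
  dn <- paste0("CC", random_dna(1, flank_len - 2))
  tract <- strrep(motif, ref_copies)
  flanked <- tibble::tibble(
    locus_id = "L1", seq_id = "r", start = 1000L,
    end = 1000L + nchar(tract), motif = motif,
    upstream = up, downstream = dn,
    query = paste0(up, tract, dn), flank_length = flank_len)
  samples <- paste0("s", seq_len(n_samples))
  obs <- lapply(samples, function(s) {
    u <- up; d <- dn
    if (!is.null(sample_flank_edits[[s]])) {
      u <- sample_flank_edits[[s]](u)
    }
    st <- strrep(motif, sample_copies)
    region <- paste0(u, st, d)
    tibble::tibble(locus_id = "L1", sample = s, status = "FOUND",
                   repeats = sample_copies, region = region,
                   run_start = nchar(u), run_end = nchar(u) + nchar(st),
                   hit_start = 0L, hit_end = nchar(region))
  })
  list(flanked = flanked, obs = dplyr::bind_rows(obs))
}

test_that("identical sample flanks give mean similarity 1", {
  fx <- make_fixture()
  fs <- flank_similarity(fx$obs, fx$flanked)
  expect_equal(fs$per_sample$flank_identity, rep(1, 5))
  expect_equal(fs$per_locus$flank_similarity, 1)
})

test_that("mismatches in one sample dilute the mean as computed by hand", {
  # 10 substitutions across 200 flank bases in one of five samples
  edit <- function(u) {
    ch <- strsplit(u, "", fixed = TRUE)[[1]]
    for (i in seq(5, 95, by = 10)) {
      ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    }
    paste(ch, collapse = "")
  }
  fx <- make_fixture(sample_flank_edits = list(s3 = edit))
  fs <- flank_similarity(fx$obs, fx$flanked)
  expect_equal(sort(unique(round(fs$per_sample$flank_identity, 4))),
               c(0.95, 1))
  expect_equal(fs$per_locus$flank_similarity, (4 * 1 + 0.95) / 5)
})

test_that("MISSING samples are excluded from the similarity mean", {
  fx <- make_fixture(n_samples = 3)
  fx$obs$status[2] <- "MISSING"
  fs <- flank_similarity(fx$obs, fx$flanked)
  expect_equal(nrow(fs$per_sample), 2L)
  expect_equal(fs$per_locus$flank_similarity, 1)
})

test_that("conserved binding sites score 100 percent", {
  fx <- make_fixture()
  primers <- design_primers(fx$flanked)
  expect_gte(nrow(primers), 1L)
  scored <- primer_binding_similarity(primers, fx$obs, fx$flanked)
  expect_true(all(scored$binding_similarity == 100))
  expect_true(all(scored$n_flagged == 0L))
})

test_that("one mismatched 20-base site in one of five samples scores 99.5", {
  fx <- make_fixture()
  primers <- design_primers(fx$flanked)[1, ]
  # place a single substitution inside the forward binding site of s2 only
  off <- primers$f_off + primers$f_len %/% 2
  edit <- function(u) {
    ch <- strsplit(u, "", fixed = TRUE)[[1]]
    ch[off + 1] <- setdiff(c("A", "C", "G", "T"), ch[off + 1])[1]
    paste(ch, collapse = "")
  }
  fx2 <- make_fixture(sample_flank_edits = list(s2 = edit))
  scored <- primer_binding_similarity(primers, fx2$obs, fx2$flanked)
  # 9 conserved sites + one with identity (len-1)/len, x100
  len <- primers$f_len
  expected <- 100 * (9 + (len - 1) / len) / 10
  expect_equal(scored$binding_similarity, expected, tolerance = 1e-6)
})

test_that("a fully deleted binding site is flagged and contributes zero", {
  fx <- make_fixture()
  primers <- design_primers(fx$flanked)[1, ]
  del <- function(u) {
    # delete the whole forward binding site
    paste0(substr(u, 1, primers$f_off),
           substr(u, primers$f_off + primers$f_len + 1, nchar(u)))
  }
  fx2 <- make_fixture(sample_flank_edits = list(s4 = del))
  scored <- primer_binding_similarity(primers, fx2$obs, fx2$flanked)
  expect_equal(scored$n_flagged, 1L)
  expect_lt(scored$binding_similarity, 100)
  expect_gte(scored$binding_similarity, 100 * 9 / 10 - 1)
})
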