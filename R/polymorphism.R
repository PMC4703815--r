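#' Genotype reference SSR loci in non-reference samples
#'
#' For every best hit, the matched target region is elongated by `elongation`
#' bases on both sides (clipped at sequence ends), reverse-complemented for
#' minus-strand hits, and scanned for the longest phase-tolerant tandem run
#' of the reference motif (see [locate_tandem_run()]). A single full motif
#' copy is enough to call the locus `FOUND`: a polymorphic array may have
#' decayed to one copy in a sample and must still be genotyped rather than
#' discarded. Zero copies gives `MISSING`; hits flagged `AMBIGUOUS` by
#' [best_hits()] stay `AMBIGUOUS` and get no repeat count.
#'
#' @param best One row per (locus, sample), from [best_hits()].
#' @param loci Reference loci (tibble with `locus_id`, `motif`).
#' @param sequences The sample's sequences searched by [search_sample()].
#' @param elongation Bases added on each side of the hit (default 50).
#' @return A tibble of allele observations: `locus_id`, `sample`, `status`
#'   (`FOUND`/`MISSING`/`AMBIGUOUS`), `repeats` (`NA` unless `FOUND`),
#'   `region` (the oriented, elongated target substring), `run_start`,
#'   `run_end` (run coordinates within `region`, 0-based half-open), and
#'   `hit_start`/`hit_end` (the hit proper within `region`, i.e. without the
#'   elongation padding).
#' @export
genotype_hits <- function(best, loci, sequences, elongation = 50L) {
  set <- as_dna_set(sequences)
  e <- as.integer(elongation)
  motif_of <- setNames(loci$motif, loci$locus_id)
  n <- nrow(best)
  status <- character(n)
  repeats <- rep(NA_integer_, n)
  region <- character(n)
  run_start <- rep(NA_integer_, n)
  run_end <- rep(NA_integer_, n)
  hit_start <- rep(NA_integer_, n)
  hit_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    tlen <- length(set[[best$seq_id[i]]])
    r0 <- max(0L, best$start[i] - e)
    r1 <- min(tlen, best$end[i] + e)
    reg <- as.character(Biostrings::subseq(set[[best$seq_id[i]]],
                                           r0 + 1L, r1))
    if (best$strand[i] == "-") reg <- revcomp(reg)
    region[i] <- reg
    # offsets of the hit proper within the oriented region (the elongation
    # padding must not be mistaken for flank sequence downstream)
    left <- best$start[i] - r0
    right <- r1 - best$end[i]
    hit_start[i] <- if (best$strand[i] == "+") left else right
    hit_end[i] <- nchar(reg) - (if (best$strand[i] == "+") right else left)
    if (best$status[i] == "AMBIGUOUS") {
      status[i] <- "AMBIGUOUS"
      next
    }
    run <- locate_tandem_run(reg, motif_of[[best$locus_id[i]]],
                             phase_tolerant = TRUE)
    if (run$repeats >= 1L) {
      status[i] <- "FOUND"
      repeats[i] <- run$repeats
      run_start[i] <- run$start
      run_end[i] <- run$end
    } else {
      status[i] <- "MISSING"
    }
  }
  tibble::tibble(locus_id = best$locus_id, sample = best$sample,
                 status = status, repeats = repeats, region = region,
                 run_start = run_start, run_end = run_end,
                 hit_start = hit_start, hit_end = hit_end)
}

#' Fill in MISSING observations for samples without a valid hit
#'
#' Ensures exactly one observation per (locus, non-reference sample); loci a
#' sample yielded no acceptable hit for are recorded as `MISSING`.
#'
#' @param observations Tibble from [genotype_hits()].
#' @param loci Reference loci tibble (`locus_id`).
#' @param samples Character vector of non-reference sample labels.
#' @return Completed observation tibble.
#' @export
complete_observations <- function(observations, loci, samples) {
  full <- tidyr::expand_grid(locus_id = loci$locus_id, sample = samples)
  if (is.null(observations) || nrow(observations) == 0L ||
      !all(c("locus_id", "sample") %in% names(observations))) {
    observations <- tibble::tibble(
      locus_id = character(), sample = character(), status = character(),
      repeats = integer(), region = character(), run_start = integer(),
      run_end = integer(), hit_start = integer(), hit_end = integer())
  }
  out <- dplyr::left_join(full, observations, by = c("locus_id", "sample"))
  out$status[is.na(out$status)] <- "MISSING"
  out
}

#' Score one locus: repeat-count dispersion and missing rate
#'
#' The polymorphism statistic ("dispersion degree") is the population
#' standard deviation (divisor n) of the repeat counts over the reference
#' allele plus all `FOUND` samples. The missing rate is the fraction of
#' non-reference samples that are `MISSING` or `AMBIGUOUS` (ambiguous hits
#' contribute to the missing rate and are excluded from the dispersion,
#' since a paralogous placement's repeat count is untrustworthy). A locus
#' passes when `sd > 0` and `mr <= 0.5`.
#'
#' @param status Status vector over the non-reference samples
#'   (`FOUND`/`MISSING`/`AMBIGUOUS`).
#' @param repeats Repeat counts matching `status` (`NA` unless `FOUND`).
#' @param ref_repeats Reference repeat count.
#' @return A one-row tibble: `sd`, `mr`, `n_found`, `n_missing`,
#'   `n_ambiguous`, `passes`.
#' @export
score_locus <- function(status, repeats, ref_repeats) {
  if (length(status) == 0L) {
    stop("score_locus needs at least one non-reference sample")
  }
  stopifnot(length(repeats) == length(status))
  found <- status == "FOUND"
  counts <- c(ref_repeats, repeats[found])
  sdev <- sqrt(mean((counts - mean(counts))^2))   # population SD, divisor n
  mr <- sum(status %in% c("MISSING", "AMBIGUOUS")) / length(status)
  tibble::tibble(sd = sdev, mr = mr, n_found = sum(found),
                 n_missing = sum(status == "MISSING"),
                 n_ambiguous = sum(status == "AMBIGUOUS"),
                 passes = sdev > 0 && mr <= 0.5)
}

#' Score all loci
#'
#' Applies [score_locus()] per locus over a completed observation table.
#'
#' @param observations Completed observations (see [complete_observations()]).
#' @param loci Reference loci tibble (`locus_id`, `repeats`).
#' @return One row per locus: `locus_id` plus the [score_locus()] columns.
#' @export
score_loci <- function(observations, loci) {
  if (nrow(observations) == 0L || nrow(loci) == 0L) {
    return(tibble::tibble(locus_id = character(), sd = double(),
                          mr = double(), n_found = integer(),
                          n_missing = integer(), n_ambiguous = integer(),
                          passes = logical()))
  }
  ref <- setNames(loci$repeats, loci$locus_id)
  observations |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::group_modify(function(g, key) {
      score_locus(g$status, g$repeats, ref[[key$locus_id]])
    }) |>
    dplyr::ungroup()
}
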