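#' Compare a pipeline result against simulator ground truth
#'
#' Matches each planted locus to candidates by reference-coordinate overlap
#' (the reported array may start one base off and at a rotated phase when a
#' flanking mutation extends it, so matching is positional, not by motif
#' string). A planted locus counts as *recovered* when it appears in the
#' candidate table and every non-dropped, non-paralog sample's genotyped
#' repeat count equals the planted count, with dropped samples reported
#' `MISSING`.
#'
#' @param result A `polyssr_result`.
#' @param sim A `polyssr_sim` (the dataset the result was computed on).
#' @return A list: `per_locus` tibble (`truth_id`, `polymorphic`,
#'   `detected`, `counts_match`, `recovered`, `locus_id`) and `stats`, a
#'   one-row tibble with `n_polymorphic`, `n_recovered`, `recovery_rate`,
#'   `n_monomorphic_reported`, `n_candidates`.
#' @export
evaluate_recovery <- function(result, sim) {
  truth <- sim$truth
  ts <- sim$truth_samples
  cand <- result$candidates
  ref_label <- result$config$reference
  # candidates are on sanitized ids "<ref>|<seq>"; truth is per "chr1"
  cand_seq <- sub("^[^|]*\\|", "", cand$seq_id)
  detected <- rep(FALSE, nrow(truth))
  counts_match <- rep(NA, nrow(truth))
  locus_id <- rep(NA_character_, nrow(truth))
  obs <- result$observations
  for (i in seq_len(nrow(truth))) {
    ov <- which(cand_seq == "chr1" &
                  cand$start < truth$ref_end[i] &
                  cand$end > truth$ref_start[i])
    if (length(ov) == 0L) next
    detected[i] <- TRUE
    lid <- cand$locus_id[ov[1L]]
    locus_id[i] <- lid
    tsi <- ts[ts$truth_id == truth$truth_id[i] & ts$sample != "REF", ,
              drop = FALSE]
    o <- obs[obs$locus_id == lid, , drop = FALSE]
    o <- o[match(tsi$sample, o$sample), , drop = FALSE]
    ok <- TRUE
    for (j in seq_len(nrow(tsi))) {
      if (tsi$paralog[j]) next                 # ambiguous by design
      if (tsi$dropped[j]) {
        ok <- ok && o$status[j] == "MISSING"
      } else {
        ok <- ok && o$status[j] == "FOUND" &&
          !is.na(o$repeats[j]) && o$repeats[j] == tsi$repeats[j]
      }
    }
    counts_match[i] <- ok
  }
  per_locus <- tibble::tibble(
    truth_id = truth$truth_id, polymorphic = truth$polymorphic,
    detected = detected, counts_match = counts_match,
    recovered = detected & !is.na(counts_match) & counts_match,
    locus_id = locus_id)
  poly <- per_locus[per_locus$polymorphic, , drop = FALSE]
  mono <- per_locus[!per_locus$polymorphic, , drop = FALSE]
  stats <- tibble::tibble(
    n_polymorphic = nrow(poly),
    n_recovered = sum(poly$recovered),
    recovery_rate = if (nrow(poly) > 0L) mean(poly$recovered) else NA_real_,
    n_monomorphic_reported = sum(mono$detected),
    n_candidates = nrow(cand))
  list(per_locus = per_locus, stats = stats)
}
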