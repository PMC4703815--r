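#' Tidy a pipeline result
#'
#' Returns the candidate PolySSR table, one row per passing locus.
#'
#' @param x A `polyssr_result`.
#' @param ... Unused.
#' @export
tidy.polyssr_result <- function(x, ...) {
  tibble::as_tibble(x$candidates)
}

#' One-row summary of a pipeline result
#'
#' @param x A `polyssr_result`.
#' @param ... Unused.
#' @export
glance.polyssr_result <- function(x, ...) {
  cand <- x$candidates
  tibble::tibble(
    n_samples = length(x$config$samples),
    n_loci_detected = nrow(x$loci),
    n_candidates = nrow(cand),
    mean_sd = if (nrow(cand)) mean(cand$sd) else NA_real_,
    mean_mr = if (nrow(cand)) mean(cand$mr) else NA_real_,
    mean_flank_similarity = if (nrow(cand)) {
      mean(cand$flank_similarity, na.rm = TRUE)
    } else NA_real_,
    primer_design_rate = if (nrow(cand)) {
      mean(cand$n_primer_pairs >= 1L)
    } else NA_real_)
}
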