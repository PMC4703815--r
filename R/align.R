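#' Alignment scoring parameters
#'
#' Scoring used by the homology search: match +1, mismatch -1, gap opening -2
#' (charged on the first gap base) and gap extension -1 per additional base.
#'
#' @param match,mismatch,gap_open,gap_ext Scores/penalties (penalties given as
#'   positive numbers).
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = 2,
                              gap_ext = 1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

# Thin R wrapper around the C++ Gotoh aligner. `fit = TRUE` gives a fitting
# alignment (a aligned end-to-end, free end gaps on b); band <= 0 disables
# banding. `exclude` is an optional 0-based half-open interval of `a` (e.g.
# an SSR tract of sample-variable length) left out of the identity/coverage
# statistics; the overall score/columns are unaffected.
align_pair <- function(a, b, scoring = alignment_scoring(), fit = FALSE,
                       band = 0L, exclude = NULL) {
  ex <- if (is.null(exclude)) c(0L, 0L) else as.integer(exclude)
  r <- c_align_pair(a, b, scoring$match, scoring$mismatch, scoring$gap_open,
                    scoring$gap_ext, fit, as.integer(band), ex[1L], ex[2L])
  if (ex[2L] > ex[1L]) {
    r$identity <- if (r$flank_columns > 0) {
      r$flank_matches / r$flank_columns
    } else 0
    flank_len <- nchar(a) - (ex[2L] - ex[1L])
    r$coverage <- if (flank_len > 0) r$flank_aligned / flank_len else 0
  } else {
    r$identity <- r$matches / r$columns
    r$coverage <- r$a_aligned / nchar(a)
  }
  r
}

#' Global alignment identity of two DNA strings
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2 per gap
#' column, no end-gap forgiveness); identity is the fraction of alignment
#' columns that are identical matches, so gap columns count against the
#' denominator. Symmetric in its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' global_identity("ACGT", "ACGA")  # 0.75
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty input")
  # linear gap cost: every gap column costs 2
  r <- align_pair(a, b, alignment_scoring(gap_open = 2, gap_ext = 2),
                  fit = FALSE, band = 0L)
  r$identity
}

# Global alignment of reference flanks vs sample flanks keeping the per-base
# column map, used to project primer binding intervals into a sample.
align_flanks <- function(ref_flanks, sample_flanks) {
  align_pair(ref_flanks, sample_flanks,
             alignment_scoring(gap_open = 2, gap_ext = 2), fit = FALSE,
             band = 0L)
}
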