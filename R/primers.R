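#' Primer design constraints
#'
#' Constraint set for the deterministic primer designer, following the
#' defaults commonly used for microsatellite marker panels: 18-24 bp primers
#' (optimum 20), melting temperature 57-63 degrees C (optimum 60), GC content
#' 40-60 percent, product size 100-300 bp, no mononucleotide run longer
#' than 4.
#'
#' @param len_min,len_opt,len_max Primer length bounds/optimum (bases).
#' @param tm_min,tm_opt,tm_max Melting temperature bounds/optimum (deg C).
#' @param gc_min,gc_max GC content bounds (percent).
#' @param product_min,product_max Product size bounds (bases).
#' @param max_tm_diff Maximum |Tm_forward - Tm_reverse| (deg C).
#' @param max_mono_run Longest allowed single-base run in a primer.
#' @export
primer_constraints <- function(len_min = 18L, len_opt = 20L, len_max = 24L,
                               tm_min = 57, tm_opt = 60, tm_max = 63,
                               gc_min = 40, gc_max = 60,
                               product_min = 100L, product_max = 300L,
                               max_tm_diff = 3, max_mono_run = 4L) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            gc_min <= gc_max, product_min <= product_max)
  list(len_min = len_min, len_opt = len_opt, len_max = len_max,
       tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
       gc_min = gc_min, gc_max = gc_max,
       product_min = product_min, product_max = product_max,
       max_tm_diff = max_tm_diff, max_mono_run = max_mono_run)
}

#' Oligo melting temperature
#'
#' Deterministic GC-count formulas: for oligos shorter than 14 bases the
#' Wallace rule `2(A+T) + 4(G+C)`; from 14 bases on,
#' `64.9 + 41 * (GC - 16.4) / length`.
#'
#' @param seq Character vector of DNA oligos (A/C/G/T, length >= 10).
#' @return Melting temperatures in degrees C.
#' @examples
#' melting_temperature("ACGTACGTACGT")  # 36
#' @export
melting_temperature <- function(seq) {
  if (any(grepl("[^ACGT]", seq))) {
    stop("melting_temperature: sequence contains non-ACGT characters")
  }
  n <- nchar(seq)
  if (any(n < 10L)) stop("melting_temperature requires length >= 10")
  gc <- nchar(gsub("[AT]", "", seq))
  at <- n - gc
  ifelse(n < 14L, 2 * at + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
}

#' GC content in percent
#' @param seq Character vector of DNA strings.
#' @export
gc_percent <- function(seq) {
  100 * nchar(gsub("[^GC]", "", seq)) / nchar(seq)
}

has_long_mono_run <- function(seq, max_run) {
  grepl(sprintf("A{%d,}|C{%d,}|G{%d,}|T{%d,}", max_run + 1L, max_run + 1L,
                max_run + 1L, max_run + 1L), seq)
}

# All candidate primers within one flank: every substring with admissible
# length, Tm, GC and run structure. Returns a tibble with 0-based [start,end)
# within the flank.
enumerate_primers <- function(flank, cs) {
  L <- nchar(flank)
  if (L < cs$len_min) {
    return(tibble::tibble(start = integer(), end = integer(),
                          seq = character()))
  }
  lens <- seq.int(cs$len_min, min(cs$len_max, L))
  cand <- dplyr::bind_rows(lapply(lens, function(len) {
    starts <- seq_len(L - len + 1L) - 1L
    tibble::tibble(start = starts, end = starts + len,
                   seq = substring(flank, starts + 1L, starts + len))
  }))
  cand <- cand[!grepl("N", cand$seq, fixed = TRUE), , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  tm <- melting_temperature(cand$seq)
  gc <- gc_percent(cand$seq)
  ok <- tm >= cs$tm_min & tm <= cs$tm_max &
    gc >= cs$gc_min & gc <= cs$gc_max &
    !has_long_mono_run(cand$seq, cs$max_mono_run)
  cand <- cand[ok, , drop = FALSE]
  cand$tm <- tm[ok]
  cand$gc <- gc[ok]
  cand
}

#' Design primer pairs on the reference flanks of SSR loci
#'
#' A deterministic constraint-based designer: all candidate forward primers
#' in the upstream flank and reverse primers (reverse complements of
#' downstream-flank substrings) satisfying the length/Tm/GC/run constraints
#' are paired subject to the product-size bounds and the maximum Tm
#' difference; pairs are ranked by
#' `penalty = |Tm_f - Tm_opt| + |Tm_r - Tm_opt|
#'  + 0.5 (|len_f - len_opt| + |len_r - len_opt|) + |Tm_f - Tm_r|`,
#' ties broken by smaller product, then leftmost forward start. Up to three
#' pairs per locus are returned; a locus for which no pair satisfies the
#' constraints is simply absent from the result ("no primer"). The product
#' spans the whole SSR tract by construction, and no binding site overlaps
#' the tract.
#'
#' @param flanked Reference loci with flanks ([extract_flanked()]); needs
#'   `locus_id`, `start`, `end`, `upstream`, `downstream`.
#' @param constraints See [primer_constraints()].
#' @param max_pairs Maximum pairs per locus (default 3).
#' @return Tibble with one row per pair: `locus_id`, `rank`, `forward`,
#'   `reverse`, `tm_f`, `tm_r`, `gc_f`, `gc_r`, `product_size`, `penalty`,
#'   reference binding intervals `f_start`, `f_end`, `r_start`, `r_end`
#'   (0-based half-open; the reverse primer is the reverse complement of
#'   `[r_start, r_end)`), and flank-local offsets `f_off`, `f_len`, `r_off`,
#'   `r_len` within the concatenated flanks.
#' @export
design_primers <- function(flanked, constraints = primer_constraints(),
                           max_pairs = 3L) {
  cs <- constraints
  out <- vector("list", nrow(flanked))
  for (i in seq_len(nrow(flanked))) {
    up <- flanked$upstream[i]
    dn <- flanked$downstream[i]
    up_len <- nchar(up)
    tract_len <- flanked$end[i] - flanked$start[i]
    fwd <- enumerate_primers(up, cs)
    rev_ <- enumerate_primers(dn, cs)
    if (nrow(fwd) == 0L || nrow(rev_) == 0L) next
    pairs <- tidyr::expand_grid(fi = seq_len(nrow(fwd)),
                                ri = seq_len(nrow(rev_)))
    product <- (up_len - fwd$start[pairs$fi]) + tract_len +
      rev_$end[pairs$ri]
    tm_diff <- abs(fwd$tm[pairs$fi] - rev_$tm[pairs$ri])
    ok <- product >= cs$product_min & product <= cs$product_max &
      tm_diff <= cs$max_tm_diff
    if (!any(ok)) next
    pairs <- pairs[ok, , drop = FALSE]
    product <- product[ok]
    tm_diff <- tm_diff[ok]
    penalty <- abs(fwd$tm[pairs$fi] - cs$tm_opt) +
      abs(rev_$tm[pairs$ri] - cs$tm_opt) +
      0.5 * (abs((fwd$end[pairs$fi] - fwd$start[pairs$fi]) - cs$len_opt) +
             abs((rev_$end[pairs$ri] - rev_$start[pairs$ri]) - cs$len_opt)) +
      tm_diff
    ord <- order(penalty, product, fwd$start[pairs$fi])
    take <- utils::head(ord, max_pairs)
    fi <- pairs$fi[take]
    ri <- pairs$ri[take]
    ref_up0 <- flanked$start[i] - up_len        # reference pos of flank start
    out[[i]] <- tibble::tibble(
      locus_id = flanked$locus_id[i],
      rank = seq_along(take),
      forward = fwd$seq[fi],
      reverse = revcomp(rev_$seq[ri]),
      tm_f = fwd$tm[fi], tm_r = rev_$tm[ri],
      gc_f = fwd$gc[fi], gc_r = rev_$gc[ri],
      product_size = product[take],
      penalty = penalty[take],
      f_start = ref_up0 + fwd$start[fi], f_end = ref_up0 + fwd$end[fi],
      r_start = flanked$end[i] + rev_$start[ri],
      r_end = flanked$end[i] + rev_$end[ri],
      f_off = fwd$start[fi], f_len = fwd$end[fi] - fwd$start[fi],
      r_off = up_len + rev_$start[ri], r_len = rev_$end[ri] - rev_$start[ri])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(locus_id = character(), rank = integer(),
                          forward = character(), reverse = character(),
                          tm_f = double(), tm_r = double(), gc_f = double(),
                          gc_r = double(), product_size = integer(),
                          penalty = double(), f_start = integer(),
                          f_end = integer(), r_start = integer(),
                          r_end = integer(), f_off = integer(),
                          f_len = integer(), r_off = integer(),
                          r_len = integer())
  }
  res
}
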