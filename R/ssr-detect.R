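#' Minimum repeat-count thresholds per motif length
#'
#' Defaults follow the thresholds in widespread use for perfect-SSR screens of
#' motif lengths 2-6: at least 6 full copies for dinucleotide motifs and 5 for
#' tri- to hexanucleotide motifs. Mononucleotide runs are never reported.
#'
#' @param di,tri,tetra,penta,hexa Minimum number of full tandem copies for
#'   motif lengths 2..6. All must be >= 2.
#' @return A named integer vector with names "2".."6".
#' @export
repeat_thresholds <- function(di = 6L, tri = 5L, tetra = 5L, penta = 5L,
                              hexa = 5L) {
  t <- c(`2` = di, `3` = tri, `4` = tetra, `5` = penta, `6` = hexa)
  t <- vapply(t, as.integer, integer(1))
  if (any(t < 2L)) stop("repeat thresholds must all be >= 2")
  t
}

#' Canonical motif class
#'
#' An SSR motif and its reverse complement describe the same locus read from
#' either strand, so motif statistics are reported per class
#' `"<m1>/<m2>"` where `m1` is the lexicographic minimum of the motif and its
#' reverse complement and `m2` the other member (`m1 == m2` for palindromic
#' motifs, rendered e.g. "TA/TA"). Rotations are deliberately not merged.
#'
#' @param motif Character vector of motifs (length 2-6, A/C/G/T only).
#' @return Character vector of class labels.
#' @examples
#' canonical_motif_class(c("GA", "CT", "TA", "GGT"))
#' @export
canonical_motif_class <- function(motif) {
  if (any(grepl("[^ACGT]", motif))) {
    stop("motif class undefined for motifs containing characters outside ACGT")
  }
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(motif)))
  m1 <- ifelse(motif <= rc, motif, rc)
  m2 <- ifelse(motif <= rc, rc, motif)
  paste0(m1, "/", m2)
}

# Motif-length class labels: di- through hexanucleotide repeats.
ssr_type_label <- function(motif_len) {
  c("2" = "DNR", "3" = "TNR", "4" = "TTR", "5" = "PNR",
    "6" = "HNR")[as.character(motif_len)]
}

#' Detect perfect SSRs in DNA sequences
#'
#' Scans each sequence for maximal perfect tandem arrays whose primitive motif
#' is 2-6 bp long and whose number of full copies meets the per-motif-length
#' threshold. Arrays are reported at their smallest (primitive) period;
#' partial trailing copies are neither counted in `repeats` nor included in
#' the locus interval. Mononucleotide runs are never reported. `N` is treated
#' as mismatching every base (including `N`), so no reported array contains
#' an `N`.
#'
#' The scan compares each sequence against itself at offsets 2..6 and
#' run-length-encodes the agreement vector: a run of `L` consecutive
#' agreements at offset `p` is a maximal period-`p` array of `L + p` bases.
#'
#' @param sequences A `DNAStringSet`, named character vector, or tibble with
#'   `seq_id` and `residues` columns.
#' @param thresholds See [repeat_thresholds()].
#' @return A tibble with columns `seq_id`, `start`, `end` (0-based half-open),
#'   `motif`, `motif_len`, `repeats`, `motif_class`, `ssr_type`, sorted by
#'   (`seq_id` in input order, `start`).
#' @export
find_ssrs <- function(sequences, thresholds = repeat_thresholds()) {
  set <- as_dna_set(sequences)
  stopifnot(identical(names(thresholds), as.character(2:6)))
  res <- purrr::map2(names(set), as.character(set), function(id, s) {
    loci <- ssr_scan_one(s, thresholds)
    if (nrow(loci) > 0L) loci$seq_id <- id
    loci
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), motif = character(),
                          motif_len = integer(), repeats = integer(),
                          motif_class = character(), ssr_type = character()))
  }
  out$motif_class <- canonical_motif_class(out$motif)
  out$ssr_type <- unname(ssr_type_label(out$motif_len))
  out$seq_ord <- match(out$seq_id, names(set))
  out <- dplyr::arrange(out, .data$seq_ord, .data$start)
  out$seq_ord <- NULL
  dplyr::relocate(out, "seq_id")
}

ssr_scan_one <- function(s, thresholds) {
  r <- charToRaw(s)
  n <- length(r)
  rawN <- charToRaw("N")
  acc <- list()
  k <- 0L
  for (p in 2:6) {
    tp <- thresholds[[as.character(p)]]
    min_run <- (tp - 1L) * p
    if (n < tp * p) next
    a <- r[seq_len(n - p)]
    b <- r[seq.int(p + 1L, n)]
    m <- (a == b) & (a != rawN)
    rl <- rle(m)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= min_run)
    for (h in hit) {
      i <- starts[h]
      L <- rl$lengths[h]
      motif <- substr(s, i, i + p - 1L)
      if (!motif_is_primitive(motif)) next
      reps <- (L + p) %/% p
      k <- k + 1L
      acc[[k]] <- c(i - 1L, i - 1L + reps * p, p, reps)
    }
  }
  if (k == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          motif = character(), motif_len = integer(),
                          repeats = integer()))
  }
  mat <- do.call(rbind, acc)
  tibble::tibble(
    start = mat[, 1L], end = mat[, 2L],
    motif = substring(s, mat[, 1L] + 1L, mat[, 1L] + mat[, 3L]),
    motif_len = mat[, 3L], repeats = mat[, 4L])
}

#' Longest tandem run of a motif within a sequence
#'
#' Counts the maximum number of consecutive full copies of `motif` found
#' anywhere in `residues`. With `phase_tolerant = TRUE` (the default, used
#' when re-detecting a reference SSR inside a homologous region whose array
#' may start at any phase) all rotations of the motif are tried and the best
#' run wins. Partial copies do not count. Returns 0 when no full copy exists.
#'
#' @param residues DNA string to scan.
#' @param motif Primitive motif of length 2-6.
#' @param phase_tolerant Try all rotations of `motif`?
#' @return Integer run length (number of full copies).
#' @seealso [locate_tandem_run()] for the run coordinates.
#' @export
count_tandem_run <- function(residues, motif, phase_tolerant = TRUE) {
  locate_tandem_run(residues, motif, phase_tolerant)$repeats
}

#' Locate the best tandem run of a motif
#'
#' Like [count_tandem_run()] but also reports where the winning run lies.
#' Ties on run length are broken towards the leftmost run, then towards the
#' earlier rotation phase.
#'
#' @inheritParams count_tandem_run
#' @return A list with `repeats`, `start`, `end` (0-based half-open; both 0
#'   when no copy exists) and `rotation` (the rotation that produced the run,
#'   `NA` when none).
#' @export
locate_tandem_run <- function(residues, motif, phase_tolerant = TRUE) {
  p <- nchar(motif)
  stopifnot(p >= 2L, p <= 6L)
  rots <- if (phase_tolerant) unique(motif_rotations(motif)) else motif
  best <- list(repeats = 0L, start = 0L, end = 0L, rotation = NA_character_)
  for (rot in rots) {
    # all (overlapping) occurrences of the rotation, via zero-width lookahead;
    # a consuming "(rot)+" scan could swallow the head of a longer run
    m <- gregexpr(paste0("(?=", rot, ")"), residues, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    pos <- as.integer(m)                    # ascending
    nxt <- match(pos + p, pos)
    runlen <- integer(length(pos))
    for (j in rev(seq_along(pos))) {
      runlen[j] <- 1L + (if (is.na(nxt[j])) 0L else runlen[nxt[j]])
    }
    j <- which.max(runlen)                  # leftmost among ties
    if (runlen[j] > best$repeats ||
        (runlen[j] == best$repeats && best$repeats > 0L &&
         pos[j] - 1L < best$start)) {
      best <- list(repeats = runlen[j], start = pos[j] - 1L,
                   end = pos[j] - 1L + runlen[j] * p, rotation = rot)
    }
  }
  best
}
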