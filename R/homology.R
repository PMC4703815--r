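#' Attach flanking sequences to SSR loci
#'
#' For every locus, extracts up to `flank_length` bases of reference sequence
#' on each side of the SSR tract. Flanks are clipped (and flagged) where the
#' locus abuts a sequence end. The concatenation
#' `upstream + tract + downstream` is the homology-search query and is a
#' verbatim substring of the reference.
#'
#' @param loci Tibble from [find_ssrs()] (reference loci).
#' @param sequences Reference sequences (`DNAStringSet`, named character, or
#'   tibble).
#' @param flank_length Flank length in bases (default 100).
#' @return `loci` with added columns `upstream`, `downstream`, `query`,
#'   `trunc_up`, `trunc_down`, `flank_length`.
#' @export
extract_flanked <- function(loci, sequences, flank_length = 100L) {
  set <- as_dna_set(sequences)
  stopifnot(all(loci$seq_id %in% names(set)))
  l <- as.integer(flank_length)
  seqs <- unname(as.character(set)[loci$seq_id])
  widths <- nchar(seqs)
  up0 <- pmax(0L, loci$start - l)
  dn1 <- pmin(widths, loci$end + l)
  loci$upstream <- substring(seqs, up0 + 1L, loci$start)
  loci$downstream <- substring(seqs, loci$end + 1L, dn1)
  loci$query <- paste0(loci$upstream,
                       substring(seqs, loci$start + 1L, loci$end),
                       loci$downstream)
  loci$trunc_up <- nchar(loci$upstream) < l
  loci$trunc_down <- nchar(loci$downstream) < l
  loci$flank_length <- l
  if (any(loci$trunc_up | loci$trunc_down)) {
    inform(sprintf("%d locus/loci have truncated flanks (sequence end)",
                   sum(loci$trunc_up | loci$trunc_down)))
  }
  loci
}

#' Search one sample's assembly for SSR flanking queries
#'
#' A self-contained seed-and-extend local search standing in for an external
#' aligner. Exact k-mer seed matches between each query and the sample's
#' sequences (both strands) are clustered by diagonal; each cluster is
#' extended by a banded global (fitting) alignment of the full query over the
#' chained span. Hits with identity `< min_identity` or query coverage
#' `< min_coverage` are discarded. No low-complexity masking of any kind is
#' applied; however, a cluster is only extended when at least one of its
#' seeds has at most `max_seed_occ` occurrences in the target sequence, which
#' stops pure SSR-tract seeds from triggering an extension at every
#' same-motif run in the genome (such extensions could never reach the
#' coverage threshold).
#'
#' Identity is counted as matches over alignment columns and coverage as the
#' fraction of query bases aligned to target bases. When the query carries an
#' SSR tract (columns `upstream`/`start`/`end` present, as produced by
#' [extract_flanked()]), the tract's alignment columns are excluded from both
#' statistics: the tract length is exactly what varies between samples, and a
#' two-copy hexanucleotide difference must not by itself push a hit below the
#' acceptance thresholds. Whether the tract is actually present in the hit is
#' decided afterwards by re-detection ([genotype_hits()]), mirroring the
#' screen-then-re-detect order of the pipeline.
#'
#' @param flanked Tibble from [extract_flanked()] with a `locus_id` column.
#' @param sequences The sample's sequences (`DNAStringSet`, named character,
#'   or tibble).
#' @param sample Sample label recorded in the hits.
#' @param seed_length k-mer seed length (>= 8, default 12).
#' @param min_identity,min_coverage Acceptance thresholds in (0, 1].
#' @param max_seed_occ Maximum target occurrences for an anchoring seed.
#' @param scoring See [alignment_scoring()].
#' @return Tibble of hits: `locus_id`, `sample`, `seq_id`, `start`, `end`
#'   (target, 0-based half-open), `strand`, `identity`, `coverage`, `score`.
#' @export
search_sample <- function(flanked, sequences, sample,
                          seed_length = 12L, min_identity = 0.95,
                          min_coverage = 0.95, max_seed_occ = 32L,
                          scoring = alignment_scoring()) {
  stopifnot(seed_length >= 8L, min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1)
  set <- as_dna_set(sequences)
  tnames <- names(set)
  k <- as.integer(seed_length)
  has_tract <- all(c("upstream", "start", "end") %in% names(flanked))

  # per (query, strand): oriented query, its k-mers and their 0-based
  # positions; all k-mers pooled into one dictionary so every target
  # sequence is scanned exactly once
  tasks <- list()
  for (qi in seq_len(nrow(flanked))) {
    q <- flanked$query[qi]
    qlen <- nchar(q)
    if (qlen < k) {
      warn(sprintf("query %s shorter than seed length; skipped",
                   flanked$locus_id[qi]))
      next
    }
    tract <- if (has_tract) {
      t0 <- nchar(flanked$upstream[qi])
      c(t0, t0 + (flanked$end[qi] - flanked$start[qi]))
    } else {
      c(0L, 0L)
    }
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") q else revcomp(q)
      tract_s <- if (strand == "+") tract else c(qlen - tract[2L],
                                                 qlen - tract[1L])
      km <- substring(qs, seq_len(qlen - k + 1L), k:qlen)
      ok <- !grepl("N", km, fixed = TRUE)
      if (!any(ok)) next
      uk <- unique(km[ok])
      tasks[[length(tasks) + 1L]] <- list(
        locus_id = flanked$locus_id[qi], strand = strand, qs = qs,
        qlen = qlen, tract = tract_s, kmers = uk,
        qpos = split(which(ok) - 1L, km[ok])[uk])
    }
  }
  out <- vector("list", length(tasks) * length(set))
  oi <- 0L
  if (length(tasks) > 0L) {
    all_kmers <- unique(unlist(lapply(tasks, `[[`, "kmers")))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_kmers))
    kmer_idx <- lapply(tasks, function(t) match(t$kmers, all_kmers))
    for (ti in seq_along(set)) {
      subject <- set[[ti]]
      tlen <- length(subject)
      if (tlen < k) next
      si <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
      occ <- lengths(si)
      if (all(occ == 0L)) next
      for (w in seq_along(tasks)) {
        tk <- tasks[[w]]
        idx <- kmer_idx[[w]]
        seeds <- seed_table(si[idx], occ[idx], tk$qpos, max_seed_occ)
        if (is.null(seeds)) next
        hits <- extend_clusters(tk$qs, subject, seeds, tk$qlen, tlen,
                                scoring, tk$tract)
        if (is.null(hits) || nrow(hits) == 0L) next
        hits <- hits[hits$identity >= min_identity &
                       hits$coverage >= min_coverage, , drop = FALSE]
        if (nrow(hits) == 0L) next
        hits$locus_id <- tk$locus_id
        hits$sample <- sample
        hits$seq_id <- tnames[ti]
        hits$strand <- tk$strand
        oi <- oi + 1L
        out[[oi]] <- hits
      }
    }
  }
  if (oi == 0L) {
    return(tibble::tibble(locus_id = character(), sample = character(),
                          seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          identity = double(), coverage = double(),
                          score = double()))
  }
  res <- dplyr::bind_rows(out[seq_len(oi)])
  res <- dplyr::select(res, "locus_id", "sample", "seq_id", "start", "end",
                       "strand", "identity", "coverage", "score")
  dplyr::arrange(res, .data$locus_id, .data$seq_id, .data$start,
                 .data$strand)
}

# Build the (qpos, tpos, anchored) seed table from matchPDict output.
seed_table <- function(start_index, occ, qpos_by_kmer, max_seed_occ) {
  nz <- which(occ > 0L)
  if (length(nz) == 0L) return(NULL)
  qp <- qpos_by_kmer[nz]
  rows <- vector("list", length(nz))
  for (j in seq_along(nz)) {
    tp <- start_index[[nz[j]]] - 1L               # 0-based target pos
    qq <- qp[[j]]
    rows[[j]] <- cbind(qpos = rep(qq, each = length(tp)),
                       tpos = rep(tp, times = length(qq)),
                       anchor = as.integer(occ[nz[j]] <= max_seed_occ))
  }
  m <- do.call(rbind, rows)
  m[order(m[, "tpos"] - m[, "qpos"], m[, "tpos"]), , drop = FALSE]
}

# Cluster seeds by diagonal, extend anchored clusters with a banded fitting
# alignment, and return de-overlapped raw hits.
extend_clusters <- function(qs, subject, seeds, qlen, tlen, scoring,
                            tract = c(0L, 0L)) {
  diag <- seeds[, "tpos"] - seeds[, "qpos"]
  gap_diag <- max(16L, qlen %/% 10L)
  brk <- c(0L, which(diff(diag) > gap_diag | abs(diff(seeds[, "tpos"])) > qlen),
           nrow(seeds))
  pad <- max(16L, as.integer(ceiling(0.05 * qlen)))
  acc <- list()
  ai <- 0L
  for (ci in seq_len(length(brk) - 1L)) {
    idx <- (brk[ci] + 1L):brk[ci + 1L]
    if (!any(seeds[idx, "anchor"] == 1L)) next
    w0 <- max(0L, min(diag[idx]) - pad)
    w1 <- min(tlen, max(diag[idx]) + qlen + pad)
    if (w1 - w0 < qlen %/% 2L) next
    win <- as.character(Biostrings::subseq(subject, w0 + 1L, w1))
    band <- (nchar(win) - qlen) + max(16L, 2L * as.integer(ceiling(0.02 * qlen)))
    r <- align_pair(qs, win, scoring, fit = TRUE, band = band,
                    exclude = if (tract[2L] > tract[1L]) tract else NULL)
    ai <- ai + 1L
    acc[[ai]] <- tibble::tibble(start = w0 + r$b_start, end = w0 + r$b_end,
                                identity = r$identity, coverage = r$coverage,
                                score = r$score)
  }
  if (ai == 0L) return(NULL)
  hits <- dplyr::bind_rows(acc)
  # the same region can be reached from several clusters: keep the best hit
  # among mutually overlapping ones (deterministic order)
  hits <- hits[order(-hits$score, -hits$identity, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    if (i < nrow(hits)) {
      for (j in (i + 1L):nrow(hits)) {
        if (!keep[j]) next
        ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
        if (ov > 0.5 * min(hits$end[i] - hits$start[i],
                           hits$end[j] - hits$start[j])) {
          keep[j] <- FALSE
        }
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Pick the best hit per locus and sample
#'
#' For each (locus, sample) group, returns the hit with maximal alignment
#' score; ties are broken by higher identity, then leftmost target interval,
#' then "+" strand. When the runner-up scores at least
#' `ambiguity_ratio * best score` the locus is flagged `AMBIGUOUS` for that
#' sample: two near-equal placements usually mean a paralogous duplication,
#' whose repeat count cannot be trusted.
#'
#' @param hits Tibble from [search_sample()] (any number of loci/samples).
#' @param ambiguity_ratio Runner-up score ratio that triggers `AMBIGUOUS`
#'   (default 0.9).
#' @return One row per (locus_id, sample) present in `hits`, with all hit
#'   columns plus `status` (`"HIT"` or `"AMBIGUOUS"`).
#' @export
best_hits <- function(hits, ambiguity_ratio = 0.9) {
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits, status = character(0)))
  }
  hits |>
    dplyr::group_by(.data$locus_id, .data$sample) |>
    dplyr::group_modify(function(g, key) {
      ord <- order(-g$score, -g$identity, g$start,
                   match(g$strand, c("+", "-")))
      g <- g[ord, , drop = FALSE]
      status <- if (nrow(g) > 1L &&
                    g$score[2L] >= ambiguity_ratio * g$score[1L]) {
        "AMBIGUOUS"
      } else "HIT"
      dplyr::mutate(g[1L, , drop = FALSE], status = status)
    }) |>
    dplyr::ungroup()
}

#' Import externally produced tabular alignment hits
#'
#' Drop-in replacement for [search_sample()] for users who prefer an external
#' aligner: reads the conventional 12-column tabular format (query id,
#' target id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, target start/end, e-value, bit score; 1-based inclusive
#' coordinates, target start > end on the minus strand) and converts it to
#' the package's hit tibble. Identity is rescaled to a fraction and coverage
#' computed as aligned query span over query length.
#'
#' @param path Path to the tabular file (no header).
#' @param flanked Tibble from [extract_flanked()] (provides query lengths).
#' @param sample Sample label for the hits.
#' @param min_identity,min_coverage Acceptance thresholds.
#' @return A hit tibble as from [search_sample()], with the bit score in the
#'   `score` column.
#' @export
read_tabular_hits <- function(path, flanked, sample, min_identity = 0.95,
                              min_coverage = 0.95) {
  cols <- c("locus_id", "seq_id", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "tstart", "tend", "evalue", "bitscore")
  tab <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  qlen <- setNames(nchar(flanked$query), flanked$locus_id)
  tab$identity <- tab$pident / 100
  tab$coverage <- (abs(tab$qend - tab$qstart) + 1) / qlen[tab$locus_id]
  tab$strand <- ifelse(tab$tend >= tab$tstart, "+", "-")
  tab$start <- as.integer(pmin(tab$tstart, tab$tend) - 1L)
  tab$end <- as.integer(pmax(tab$tstart, tab$tend))
  tab$sample <- sample
  tab$score <- tab$bitscore
  tab <- tab[tab$identity >= min_identity & tab$coverage >= min_coverage, ]
  dplyr::arrange(
    dplyr::select(tibble::as_tibble(tab), "locus_id", "sample", "seq_id",
                  "start", "end", "strand", "identity", "coverage", "score"),
    .data$locus_id, .data$seq_id, .data$start, .data$strand)
}
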