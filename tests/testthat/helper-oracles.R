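# Independent oracles used by the test suite. These deliberately take
# different algorithmic routes than the package implementation.

# Reverse complement without Biostrings (checks canonical_motif_class).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_primitive <- function(motif) {
  p <- nchar(motif)
  for (d in seq_len(p - 1)) {
    if (p %% d == 0 && motif == strrep(substr(motif, 1, d), p / d)) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force SSR enumerator: tries the candidate motif at every position and
# period, counts full copies forward by substring comparison, and keeps
# left-maximal, primitive, threshold-passing arrays. Independent of the
# rle-of-offset-agreement route used by find_ssrs().
oracle_find_ssrs <- function(s, thresholds = repeat_thresholds()) {
  n <- nchar(s)
  out <- list()
  oi <- 0
  for (p in 2:6) {
    tp <- thresholds[[as.character(p)]]
    if (n < p * tp) next
    km <- substring(s, 1:(n - p + 1), p:n)
    idx <- seq_len(n - 2 * p + 1)
    cand <- idx[km[idx] == km[idx + p] & !grepl("N", km[idx], fixed = TRUE)]
    for (i in cand) {
      motif <- km[i]
      # left-maximality: the array must not extend one base to the left
      if (i > 1) {
        prev <- substr(s, i - 1, i - 1)
        if (prev != "N" && prev == substr(s, i + p - 1, i + p - 1)) next
      }
      if (!oracle_primitive(motif)) next
      r <- 1
      while (i + (r + 1) * p - 1 <= n && km[i + r * p] == motif) r <- r + 1
      if (r < tp) next
      region <- substr(s, i, i - 1 + r * p)
      if (grepl("N", region, fixed = TRUE)) next
      oi <- oi + 1
      out[[oi]] <- data.frame(start = i - 1, end = i - 1 + r * p,
                              motif = motif, repeats = r)
    }
  }
  if (oi == 0) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), repeats = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, nchar(res$motif)), , drop = FALSE]
}

# Exhaustive tandem-run scan: for every rotation of the motif and every start
# position, count consecutive full copies by direct substring comparison.
oracle_tandem_run <- function(residues, motif) {
  p <- nchar(motif)
  n <- nchar(residues)
  rots <- vapply(seq_len(p) - 1, function(i) {
    paste0(substr(motif, i + 1, p), substr(motif, 1, i))
  }, character(1))
  best <- 0
  for (rot in unique(rots)) {
    for (i in seq_len(max(0, n - p + 1))) {
      r <- 0
      while (i + (r + 1) * p - 1 <= n &&
             substr(residues, i + r * p, i + (r + 1) * p - 1) == rot) {
        r <- r + 1
      }
      best <- max(best, r)
    }
  }
  best
}

# Biostrings-based alignment oracles with the package's scoring
# (match +1, mismatch -1; gap of length L costs open + (L-1) * ext).
oracle_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

oracle_global_score <- function(a, b, gap_open = 2, gap_ext = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = oracle_submat(),
    gapOpening = gap_open - gap_ext, gapExtension = gap_ext,
    type = "global", scoreOnly = TRUE)
}

oracle_local_alignment <- function(a, b, gap_open = 2, gap_ext = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = oracle_submat(),
    gapOpening = gap_open - gap_ext, gapExtension = gap_ext,
    type = "local")
  list(score = Biostrings::score(al),
       identity = Biostrings::nmatch(al) / Biostrings::nchar(al),
       coverage = Biostrings::width(Biostrings::pattern(al)) / nchar(a),
       t_start = Biostrings::start(Biostrings::subject(al)) - 1,
       t_end = Biostrings::end(Biostrings::subject(al)))
}

# Plant substitutions/indels into a sequence (test fixture builder).
mutate_dna <- function(s, n_sub = 0, n_ins = 0, n_del = 0) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (n_sub > 0) {
    at <- sample(length(ch), n_sub)
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  if (n_ins > 0) {
    for (k in seq_len(n_ins)) {
      at <- sample(length(ch), 1)
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = at)
    }
  }
  if (n_del > 0) {
    ch <- ch[-sample(length(ch), n_del)]
  }
  paste(ch, collapse = "")
}

# Small, fast simulator configuration for unit tests.
small_sim_config <- function(seed = 7, noiseless = FALSE, ...) {
  base <- list(seed = seed, n_samples = 4L, seq_length = 60000L,
               n_loci = 12L, frac_polymorphic = 0.5)
  if (noiseless) {
    base <- c(base, list(flank_sub_rate = 0, flank_indel_rate = 0,
                         dropout_prob = 0))
  }
  do.call(sim_config, utils::modifyList(base, list(...)))
}
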