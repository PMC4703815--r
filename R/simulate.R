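#' Configuration for the synthetic-assembly simulator
#'
#' Describes a multi-sample study in which a shared random background genome
#' carries planted SSR loci whose repeat counts vary per sample. Defaults
#' emulate a six-assembly screen (one reference plus five others, 1 Mb each)
#' with one hundred planted loci, half of them polymorphic, repeat-count
#' offsets of up to two copies either way, light flanking mutation
#' (substitution 0.005/base, indel 0.001/base within the flanks) and 5%
#' per-sample locus dropout. Paralogous duplication is off by default and is
#' exercised by dedicated scenarios.
#'
#' @param seed Random seed; generation is fully deterministic given the seed.
#' @param n_samples Total samples including the reference (>= 2).
#' @param seq_length Length of the single chromosome per sample (bases).
#' @param n_loci Number of planted SSR loci.
#' @param frac_polymorphic Fraction of planted loci that are polymorphic.
#' @param offset_range Integer range for per-sample repeat-count offsets;
#'   polymorphic loci redraw until not all offsets are zero, monomorphic loci
#'   use all-zero offsets. Offsets are clamped so counts stay >= 1.
#' @param flank_sub_rate,flank_indel_rate Per-base mutation rates applied to
#'   the `flank_length` bases on each side of a planted tract, in
#'   non-reference samples only.
#' @param dropout_prob Probability that a (locus, sample) is deleted
#'   (tract plus both flanks removed).
#' @param paralog_prob Probability that a (locus, sample) additionally
#'   receives an identical-flank duplicate elsewhere in the assembly,
#'   forcing an ambiguous homology call.
#' @param flank_length Flank window size used for spacing and mutation.
#' @param motif_lengths Motif lengths to draw planted motifs from.
#' @param thresholds Detection thresholds (reference counts are planted
#'   above them); see [repeat_thresholds()].
#' @return A `polyssr_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 6L, seq_length = 1e6,
                       n_loci = 100L, frac_polymorphic = 0.5,
                       offset_range = c(-2L, 2L),
                       flank_sub_rate = 0.005, flank_indel_rate = 0.001,
                       dropout_prob = 0.05, paralog_prob = 0,
                       flank_length = 100L, motif_lengths = 2:6,
                       thresholds = repeat_thresholds()) {
  stopifnot(n_samples >= 2L, n_loci >= 1L,
            frac_polymorphic >= 0, frac_polymorphic <= 1,
            all(c(flank_sub_rate, flank_indel_rate, dropout_prob,
                  paralog_prob) >= 0),
            all(c(flank_sub_rate, flank_indel_rate, dropout_prob,
                  paralog_prob) <= 1),
            offset_range[1] <= offset_range[2])
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         seq_length = as.integer(seq_length), n_loci = as.integer(n_loci),
         frac_polymorphic = frac_polymorphic,
         offset_range = as.integer(offset_range),
         flank_sub_rate = flank_sub_rate,
         flank_indel_rate = flank_indel_rate,
         dropout_prob = dropout_prob, paralog_prob = paralog_prob,
         flank_length = as.integer(flank_length),
         motif_lengths = as.integer(motif_lengths),
         thresholds = thresholds),
    class = "polyssr_sim_config")
}

# Draw one random primitive motif of the given length.
random_primitive_motif <- function(len) {
  repeat {
    m <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (motif_is_primitive(m)) return(m)
  }
}

# Apply substitutions and short (1-3 bp) indels to a DNA string.
mutate_flank <- function(seq, sub_rate, indel_rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n == 0L) return(seq)
  sub_at <- which(stats::runif(n) < sub_rate)
  for (i in sub_at) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  indel_at <- which(stats::runif(n) < indel_rate)
  if (length(indel_at) > 0L) {
    pieces <- as.list(ch)
    for (i in indel_at) {
      size <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        pieces[[i]] <- c(sample(DNA_BASES, size, replace = TRUE), pieces[[i]])
      } else {
        drop <- i:min(n, i + size - 1L)
        for (d in drop) pieces[[d]] <- character(0)
      }
    }
    ch <- unlist(pieces)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic multi-sample study with known truth
#'
#' Builds one reference assembly plus `n_samples - 1` mutated assemblies over
#' a shared i.i.d.-uniform background. Each planted locus inserts
#' `motif x reference_count` into the reference and
#' `motif x (reference_count + offset)` into each sample at the homologous
#' position; flank mutations, dropout and paralog duplication are applied
#' per configuration. The two background bases adjacent to each tract are
#' pinned (identically in all samples) so the background can never extend a
#' planted array, keeping the planted coordinates and counts exact.
#'
#' @param config A [sim_config()].
#' @return A list of class `polyssr_sim`: `samples` (a [sample_set()],
#'   reference labelled `"REF"`), `truth` (per-locus tibble: `truth_id`,
#'   `motif`, `motif_len`, `ref_repeats`, `ref_start`, `ref_end`,
#'   `polymorphic`), and `truth_samples` (long tibble: `truth_id`, `sample`,
#'   `repeats` (`NA` when dropped), `dropped`, `paralog`, `tract_start`).
#' @export
simulate_assemblies <- function(config) {
  stopifnot(inherits(config, "polyssr_sim_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    l <- cf$flank_length
    P <- cf$n_loci
    max_tract <- (max(unlist(cf$thresholds)) + 6L) * 6L
    spacing <- cf$seq_length %/% (P + 1L)
    # jitter can bring neighbours up to spacing/2 close
    if (spacing %/% 2L < 2L * l + max_tract + 20L) {
      stop("cannot place ", P, " loci with >= ", 2L * l,
           " bp spacing in ", cf$seq_length, " bp")
    }
    bg <- sample(DNA_BASES, cf$seq_length, replace = TRUE)
    jitter <- sample(-(spacing %/% 4L):(spacing %/% 4L), P, replace = TRUE)
    pos <- spacing * seq_len(P) + jitter      # insertion points, 0-based
    # loci
    mlen <- cf$motif_lengths[sample.int(length(cf$motif_lengths), P,
                                        replace = TRUE)]
    motifs <- vapply(mlen, random_primitive_motif, character(1))
    ref_reps <- vapply(mlen, function(p) {
      cf$thresholds[[as.character(p)]] + sample(1:5, 1L)
    }, integer(1))
    n_poly <- round(P * cf$frac_polymorphic)
    poly <- sample(rep(c(TRUE, FALSE), c(n_poly, P - n_poly)))
    # pin the background bases flanking each tract so arrays cannot extend
    for (i in seq_len(P)) {
      last <- substr(motifs[i], mlen[i], mlen[i])
      first <- substr(motifs[i], 1L, 1L)
      if (bg[pos[i]] == last) bg[pos[i]] <- sample(setdiff(DNA_BASES, last), 1L)
      if (bg[pos[i] + 1L] == first) {
        bg[pos[i] + 1L] <- sample(setdiff(DNA_BASES, first), 1L)
      }
    }
    samples <- c("REF", paste0("S", seq_len(cf$n_samples - 1L)))
    nonref <- samples[-1L]
    # per-sample offsets
    offs <- matrix(0L, nrow = P, ncol = length(nonref),
                   dimnames = list(NULL, nonref))
    off_vals <- cf$offset_range[1]:cf$offset_range[2]
    for (i in which(poly)) {
      repeat {
        o <- off_vals[sample.int(length(off_vals), length(nonref),
                                 replace = TRUE)]
        o <- pmax(o, 1L - ref_reps[i])        # clamp counts to >= 1
        if (any(o != 0L)) break
      }
      offs[i, ] <- o
    }
    dropped <- matrix(stats::runif(P * length(nonref)) < cf$dropout_prob,
                      nrow = P, dimnames = list(NULL, nonref))
    paralog <- matrix(stats::runif(P * length(nonref)) < cf$paralog_prob,
                      nrow = P, dimnames = list(NULL, nonref))
    bg_str <- paste(bg, collapse = "")

    seqs <- list()
    truth_samples <- list()
    for (s in samples) {
      is_ref <- s == "REF"
      pieces <- character(0)
      cursor <- 0L          # consumed background, 0-based
      tract_starts <- rep(NA_integer_, P)
      out_len <- 0L
      extras <- character(0)
      for (i in seq_len(P)) {
        seg <- substr(bg_str, cursor + 1L, pos[i] - l)
        up <- substr(bg_str, pos[i] - l + 1L, pos[i])
        dn <- substr(bg_str, pos[i] + 1L, pos[i] + l)
        cursor <- pos[i] + l
        reps <- if (is_ref) ref_reps[i] else ref_reps[i] + offs[i, s]
        tract <- strrep(motifs[i], reps)
        if (!is_ref) {
          up <- mutate_flank(up, cf$flank_sub_rate, cf$flank_indel_rate)
          dn <- mutate_flank(dn, cf$flank_sub_rate, cf$flank_indel_rate)
        }
        if (!is_ref && dropped[i, s]) {
          pieces <- c(pieces, seg)
          out_len <- out_len + nchar(seg)
          next
        }
        tract_starts[i] <- out_len + nchar(seg) + nchar(up)
        pieces <- c(pieces, seg, up, tract, dn)
        out_len <- out_len + nchar(seg) + nchar(up) + nchar(tract) + nchar(dn)
        if (!is_ref && paralog[i, s]) {
          extras <- c(extras, random_dna(1L, 2L * l), up, tract, dn)
        }
      }
      tail_seg <- substr(bg_str, cursor + 1L, cf$seq_length)
      pieces <- c(pieces, tail_seg, extras)
      seqs[[s]] <- setNames(paste(pieces, collapse = ""), "chr1")
      # realized per-sample repeat counts: a flanking mutation can extend or
      # (rarely) truncate a planted array, so the truth records the tandem
      # run actually present in the emitted sequence, not the nominal count
      planted <- if (is_ref) ref_reps else ref_reps + offs[, s]
      reps_s <- rep(NA_integer_, P)
      for (i in seq_len(P)) {
        if (!is_ref && dropped[i, s]) next
        w0 <- max(0L, tract_starts[i] - 12L)
        w1 <- tract_starts[i] + planted[i] * mlen[i] + 12L
        reps_s[i] <- count_tandem_run(substr(seqs[[s]], w0 + 1L, w1),
                                      motifs[i], phase_tolerant = TRUE)
      }
      truth_samples[[s]] <- tibble::tibble(
        truth_id = sprintf("L%03d", seq_len(P)), sample = s,
        repeats = reps_s,
        dropped = if (is_ref) FALSE else dropped[, s],
        paralog = if (is_ref) FALSE else paralog[, s],
        tract_start = tract_starts)
    }
    truth_samples <- dplyr::bind_rows(truth_samples)
    # polymorphic status accounting for dropout: > 1 distinct count among
    # the reference and the surviving samples
    truth <- tibble::tibble(
      truth_id = sprintf("L%03d", seq_len(P)),
      motif = motifs, motif_len = mlen, ref_repeats = ref_reps,
      ref_start = NA_integer_, ref_end = NA_integer_,
      polymorphic = NA)
    ref_rows <- truth_samples[truth_samples$sample == "REF", ]
    truth$ref_start <- ref_rows$tract_start[match(truth$truth_id,
                                                  ref_rows$truth_id)]
    truth$ref_end <- truth$ref_start + truth$ref_repeats * truth$motif_len
    obs_counts <- truth_samples[!is.na(truth_samples$repeats), ] |>
      dplyr::group_by(.data$truth_id) |>
      dplyr::summarise(k = dplyr::n_distinct(.data$repeats))
    truth$polymorphic <- obs_counts$k[match(truth$truth_id,
                                            obs_counts$truth_id)] > 1L
    ss <- sample_set(seqs, reference = "REF")
    structure(list(samples = ss, truth = truth,
                   truth_samples = truth_samples, config = cf),
              class = "polyssr_sim")
  })
}

#' Fixed benchmark scenario: a decaying hexanucleotide array
#'
#' A deterministic six-sample dataset holding a single CCACGG locus whose
#' array has five copies in the reference, four in three samples and three
#' in another, while the last sample carries two substitutions inside the
#' array that leave only one continuous copy intact. Flanks are fully
#' conserved. A correct pipeline reports this locus as a passing candidate
#' with repeat counts {5, 4, 4, 4, 3, 1}, a positive dispersion and a
#' missing rate of zero, and its primer binding regions as completely
#' conserved.
#'
#' @return A `polyssr_sim` list (see [simulate_assemblies()]); the truth
#'   tibbles mark the locus polymorphic with the per-sample counts above
#'   (the substitution-broken sample is listed with its single intact copy).
#' @export
scenario_cpssr4933 <- function() {
  withr::with_seed(4933L, {
    motif <- "CCACGG"
    bg <- random_dna(1L, 4000L)
    # pin the junction bases so the background cannot extend the array
    substr(bg, 2000L, 2000L) <- "T"   # != last motif base G
    substr(bg, 2001L, 2001L) <- "A"   # != first motif base C
    left <- substr(bg, 1L, 2000L)
    right <- substr(bg, 2001L, 4000L)
    counts <- c(REF = 5L, S1 = 4L, S2 = 4L, S3 = 4L, S4 = 3L, S5 = 5L)
    seqs <- lapply(names(counts), function(s) {
      tract <- strrep(motif, counts[[s]])
      if (s == "S5") {
        # substitutions at the first base of copies 2 and 4 leave a single
        # intact copy in every rotation phase
        substr(tract, 7L, 7L) <- "T"
        substr(tract, 19L, 19L) <- "T"
      }
      setNames(paste0(left, tract, right), "chr1")
    })
    names(seqs) <- names(counts)
    ss <- sample_set(seqs, reference = "REF")
    eff <- c(REF = 5L, S1 = 4L, S2 = 4L, S3 = 4L, S4 = 3L, S5 = 1L)
    truth <- tibble::tibble(
      truth_id = "L001", motif = motif, motif_len = 6L, ref_repeats = 5L,
      ref_start = 2000L, ref_end = 2000L + 30L, polymorphic = TRUE)
    truth_samples <- tibble::tibble(
      truth_id = "L001", sample = names(counts),
      repeats = unname(eff), dropped = FALSE, paralog = FALSE,
      tract_start = 2000L)
    structure(list(samples = ss, truth = truth,
                   truth_samples = truth_samples,
                   config = NULL),
              class = "polyssr_sim")
  })
}

#' Write a simulated study to disk
#'
#' One FASTA per sample plus a tab-separated truth table.
#'
#' @param sim A `polyssr_sim` from [simulate_assemblies()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in sim$samples$samples) {
    p <- file.path(dir, paste0(s, ".fasta"))
    write_fasta(sim$samples$sequences[[s]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  readr::write_tsv(dplyr::left_join(sim$truth_samples, sim$truth,
                                    by = "truth_id"), tp)
  invisible(c(paths, tp))
}
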