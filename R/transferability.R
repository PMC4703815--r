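#' Flanking-sequence similarity across samples
#'
#' For every `FOUND` observation of a locus, the SSR tract (the genotyped
#' run) is excised from the sample's region and the remaining concatenated
#' flanks are globally aligned against the reference flanks
#' (`upstream + downstream`); the per-sample identity and the per-locus mean
#' are reported. High flank similarity predicts that primers designed on the
#' reference will transfer to the other assemblies.
#'
#' @param observations Completed observations (with `region`, `run_start`,
#'   `run_end`), see [genotype_hits()].
#' @param flanked Reference loci with flanks, see [extract_flanked()].
#' @return A list with `per_sample` (tibble: `locus_id`, `sample`,
#'   `flank_identity`) and `per_locus` (tibble: `locus_id`,
#'   `flank_similarity` = mean over `FOUND` samples, `NA` when none).
#' @export
flank_similarity <- function(observations, flanked) {
  found <- observations[observations$status == "FOUND", , drop = FALSE]
  ref_flanks <- setNames(paste0(flanked$upstream, flanked$downstream),
                         flanked$locus_id)
  ident <- numeric(nrow(found))
  for (i in seq_len(nrow(found))) {
    sflank <- sample_flanks(found[i, ])
    rflank <- ref_flanks[[found$locus_id[i]]]
    ident[i] <- if (nzchar(sflank) && nzchar(rflank)) {
      global_identity(rflank, sflank)
    } else {
      NA_real_
    }
  }
  per_sample <- tibble::tibble(locus_id = found$locus_id,
                               sample = found$sample,
                               flank_identity = ident)
  per_locus <- per_sample |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(flank_similarity = mean(.data$flank_identity,
                                             na.rm = TRUE)) |>
    dplyr::ungroup()
  list(per_sample = per_sample, per_locus = per_locus)
}

# Sample-side flanks: the hit region (without the elongation padding) with
# the genotyped SSR run excised. `obs` is a one-row FOUND observation.
sample_flanks <- function(obs) {
  left_end <- max(obs$hit_start, min(obs$run_start, obs$hit_end))
  right_start <- min(obs$hit_end, max(obs$run_end, obs$hit_start))
  paste0(substr(obs$region, obs$hit_start + 1L, left_end),
         substr(obs$region, right_start + 1L, obs$hit_end))
}

#' Conservation of primer binding regions across samples
#'
#' For each primer pair of a locus, the reference flanks are globally aligned
#' to each `FOUND` sample's flanks; the alignment column map projects each
#' primer's binding interval into the sample, and the homologous sample
#' subsequence is compared to the reference binding region by
#' [global_identity()]. The score is the mean over both primers and all
#' `FOUND` samples, scaled to a percentage; 100 means the binding sites are
#' completely conserved, the condition under which cross-sample PCR
#' amplification is most likely to succeed. A binding site whose projection
#' is fully deleted in a sample contributes 0 and is counted in `n_flagged`.
#'
#' @param primers Primer table from [design_primers()] (columns `locus_id`,
#'   `rank`, `f_off`, `f_len`, `r_off`, `r_len` locate the binding sites
#'   within the concatenated reference flanks).
#' @param observations Completed observations (for the sample flanks).
#' @param flanked Reference loci with flanks.
#' @return `primers` with added columns `binding_similarity` (percentage,
#'   `NA` when no sample is `FOUND`) and `n_flagged`.
#' @export
primer_binding_similarity <- function(primers, observations, flanked) {
  if (nrow(primers) == 0L) {
    primers$binding_similarity <- double(0)
    primers$n_flagged <- integer(0)
    return(primers)
  }
  found <- observations[observations$status == "FOUND", , drop = FALSE]
  ref_flanks <- setNames(paste0(flanked$upstream, flanked$downstream),
                         flanked$locus_id)
  # one flank alignment per (locus, sample), reused by all primer pairs
  maps <- list()
  for (i in seq_len(nrow(found))) {
    keyi <- paste0(found$locus_id[i], "\r", found$sample[i])
    sflank <- sample_flanks(found[i, ])
    rflank <- ref_flanks[[found$locus_id[i]]]
    if (!nzchar(sflank) || !nzchar(rflank)) next
    al <- align_flanks(rflank, sflank)
    maps[[keyi]] <- list(map = al$map_a, sflank = sflank)
  }
  sim <- rep(NA_real_, nrow(primers))
  nflag <- rep(0L, nrow(primers))
  for (i in seq_len(nrow(primers))) {
    lid <- primers$locus_id[i]
    samples <- found$sample[found$locus_id == lid]
    if (length(samples) == 0L) next
    rflank <- ref_flanks[[lid]]
    vals <- c()
    flags <- 0L
    for (s in samples) {
      m <- maps[[paste0(lid, "\r", s)]]
      if (is.null(m)) next
      for (side in c("f", "r")) {
        off <- primers[[paste0(side, "_off")]][i]
        len <- primers[[paste0(side, "_len")]][i]
        ref_site <- substr(rflank, off + 1L, off + len)
        bpos <- m$map[(off + 1L):(off + len)]
        bpos <- bpos[!is.na(bpos)]
        if (length(bpos) < 0.5 * len) {
          # binding site (essentially) deleted in this sample; a base or two
          # can still map when the aligner wiggles the gap ends
          vals <- c(vals, 0)
          flags <- flags + 1L
        } else {
          site <- substr(m$sflank, min(bpos), max(bpos))
          vals <- c(vals, global_identity(ref_site, site))
        }
      }
    }
    if (length(vals) > 0L) {
      sim[i] <- 100 * mean(vals)
      nflag[i] <- flags
    }
  }
  primers$binding_similarity <- sim
  primers$n_flagged <- nflag
  primers
}
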