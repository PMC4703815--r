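#' Write pipeline outputs
#'
#' Writes the candidate table (`CandidatePolySSRs.tsv`), per-sample flank
#' sequences (`Flanks.fasta`, headers `<locus_id>|<sample>`, 60-column
#' wrapped), the primer table (`Primers.tsv`), summary statistics
#' (`Summary.tsv`) and a log with the full configuration echo (`run.log`).
#' Coordinates in the TSVs are 1-based inclusive; the missing rate is
#' rendered as a percentage with two decimals. Empty results produce
#' header-only tables. Outputs contain no timestamps, so identical runs
#' write byte-identical files.
#'
#' @param result A `polyssr_result` from [polyssr_run()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "polyssr_result"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  cand <- result$candidates
  nonref <- setdiff(result$config$samples, result$config$reference)
  rep_cols <- paste0("repeats_", nonref)
  tab <- tibble::tibble(
    locus_id = cand$locus_id, seq_id = cand$seq_id,
    start = cand$start + 1L, end = cand$end,      # 1-based inclusive
    motif = cand$motif, motif_class = cand$motif_class,
    ssr_type = cand$ssr_type,
    repeats_ref = cand$repeats)
  for (cc in rep_cols) {
    tab[[cc]] <- if (cc %in% names(cand)) cand[[cc]] else NA_character_
  }
  tab$SD <- sprintf("%.4f", cand$sd)
  tab$MR_percent <- sprintf("%.2f", 100 * cand$mr)
  tab$flank_similarity <- sprintf("%.4f", cand$flank_similarity)
  tab$n_primer_pairs <- cand$n_primer_pairs
  if ("region" %in% names(cand)) tab$region <- cand$region
  p_cand <- file.path(outdir, "CandidatePolySSRs.tsv")
  readr::write_tsv(tab, p_cand, na = "NA")

  # flank FASTA: reference query plus each FOUND sample's region
  p_fa <- file.path(outdir, "Flanks.fasta")
  fl <- result$flanked
  seqs <- character(0)
  if (nrow(fl) > 0L) {
    seqs <- setNames(fl$query,
                     paste0(fl$locus_id, "|", result$config$reference))
    obs <- result$observations
    obs <- obs[obs$status == "FOUND" & obs$locus_id %in% fl$locus_id, ,
               drop = FALSE]
    if (nrow(obs) > 0L) {
      more <- setNames(obs$region, paste0(obs$locus_id, "|", obs$sample))
      seqs <- c(seqs, more)
    }
  }
  if (length(seqs) > 0L) {
    write_fasta(seqs, p_fa)
  } else {
    file.create(p_fa)
  }

  p_primers <- file.path(outdir, "Primers.tsv")
  pr <- result$primers
  ptab <- tibble::tibble(
    locus_id = pr$locus_id, rank = pr$rank,
    forward = pr$forward, reverse = pr$reverse,
    Tm_f = sprintf("%.2f", pr$tm_f), Tm_r = sprintf("%.2f", pr$tm_r),
    GC_f = sprintf("%.2f", pr$gc_f), GC_r = sprintf("%.2f", pr$gc_r),
    product_size = pr$product_size,
    penalty = sprintf("%.3f", pr$penalty),
    binding_similarity_percent = ifelse(is.na(pr$binding_similarity), "NA",
                                        sprintf("%.2f",
                                                pr$binding_similarity)))
  readr::write_tsv(ptab, p_primers, na = "NA")

  p_sum <- file.path(outdir, "Summary.tsv")
  s <- result$summary
  stab <- tibble::tibble(
    section = s$section, label = s$label,
    n = ifelse(is.na(s$n), "NA", as.character(s$n)),
    value = ifelse(is.na(s$value), "NA", sprintf("%.2f", s$value)))
  readr::write_tsv(stab, p_sum, na = "NA")

  p_log <- file.path(outdir, "run.log")
  writeLines(result$log, p_log)
  invisible(c(p_cand, p_fa, p_primers, p_sum, p_log))
}
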