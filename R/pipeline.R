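#' Run the full PolySSR discovery pipeline
#'
#' End-to-end orchestration: sanitize headers, detect reference SSRs, attach
#' flanks, locate homologs in every non-reference sample, genotype the motif
#' in each hit region, score repeat-count dispersion (SD) and missing rate
#' (MR), keep loci with `SD > 0` and `MR <= 50%`, measure flank similarity,
#' design primer pairs and score their binding-region conservation, and
#' (optionally) classify loci by genomic region. Locus serials `CPSSR_<n>`
#' are assigned in reference coordinate order. The run is fully deterministic
#' for a given input and configuration, independent of `workers`.
#'
#' @param samples A [sample_set()].
#' @param flank_length Flank length for homology queries (default 100; must
#'   be at least the maximum primer length).
#' @param elongation Bases added around each hit before re-detecting the
#'   motif (default 50).
#' @param min_identity,min_coverage Homology acceptance thresholds (MI/MC,
#'   default 0.95 each).
#' @param seed_length k-mer seed length for the search (default 12).
#' @param ambiguity_ratio Runner-up score ratio flagging paralogs
#'   (default 0.9).
#' @param thresholds SSR detection thresholds ([repeat_thresholds()]).
#' @param constraints Primer constraints ([primer_constraints()]).
#' @param gene_models Optional tibble from [read_gff_genes()]; locus seq_ids
#'   have their sample prefix stripped before matching annotation seq_ids.
#' @param workers Number of parallel workers for the per-sample search
#'   (forked; results are merged in deterministic order).
#' @return An object of class `polyssr_result` with elements `candidates`
#'   (passing loci, one row each), `loci` (all detected reference SSRs with
#'   scores), `observations`, `flank_identity` (per sample),
#'   `primers`, `summary`, `config`, `renames` and `log`.
#' @export
polyssr_run <- function(samples,
                        flank_length = 100L, elongation = 50L,
                        min_identity = 0.95, min_coverage = 0.95,
                        seed_length = 12L, ambiguity_ratio = 0.9,
                        thresholds = repeat_thresholds(),
                        constraints = primer_constraints(),
                        gene_models = NULL, workers = 1L) {
  stopifnot(inherits(samples, "polyssr_sample_set"))
  if (flank_length < constraints$len_max) {
    stop("flank_length must be >= the maximum primer length (",
         constraints$len_max, ")")
  }
  if (length(samples$samples) < 2L) stop("need at least one non-reference sample")
  config <- list(flank_length = as.integer(flank_length),
                 elongation = as.integer(elongation),
                 min_identity = min_identity, min_coverage = min_coverage,
                 seed_length = as.integer(seed_length),
                 ambiguity_ratio = ambiguity_ratio,
                 thresholds = thresholds, constraints = constraints,
                 workers = as.integer(workers),
                 reference = samples$reference,
                 samples = samples$samples)
  log_lines <- c("polyssr run", config_echo(config))

  ss <- sanitize_headers(samples)
  ref <- ss$reference
  nonref <- setdiff(ss$samples, ref)
  ref_seqs <- ss$sequences[[ref]]

  loci <- find_ssrs(ref_seqs, thresholds)
  log_lines <- c(log_lines,
                 sprintf("detected %d reference SSR loci", nrow(loci)))
  if (nrow(loci) == 0L) {
    warn("no SSRs detected on the reference; outputs will be empty")
  }
  loci$locus_id <- sprintf("CPSSR_%d", seq_len(nrow(loci)))
  loci$sample <- ref
  flanked <- extract_flanked(loci, ref_seqs, flank_length)

  search_one <- function(s) {
    search_sample(flanked, ss$sequences[[s]], s,
                  seed_length = seed_length, min_identity = min_identity,
                  min_coverage = min_coverage)
  }
  hit_list <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(nonref, search_one, mc.cores = workers)
  } else {
    lapply(nonref, search_one)
  }
  hits <- dplyr::bind_rows(hit_list)
  best <- best_hits(hits, ambiguity_ratio)

  obs_list <- lapply(nonref, function(s) {
    b <- best[best$sample == s, , drop = FALSE]
    if (nrow(b) == 0L) return(NULL)
    genotype_hits(b, loci, ss$sequences[[s]], elongation)
  })
  observations <- complete_observations(dplyr::bind_rows(obs_list), loci,
                                        nonref)
  scores <- score_loci(observations, loci)
  loci <- dplyr::left_join(loci, scores, by = "locus_id")

  passing <- loci[loci$passes, , drop = FALSE]
  log_lines <- c(log_lines,
                 sprintf("%d locus/loci pass SD > 0 and MR <= 50%%",
                         nrow(passing)))
  obs_pass <- observations[observations$locus_id %in% passing$locus_id, ,
                           drop = FALSE]
  flanked_pass <- flanked[flanked$locus_id %in% passing$locus_id, ,
                          drop = FALSE]
  fsim <- flank_similarity(obs_pass, flanked_pass)
  primers <- design_primers(flanked_pass, constraints)
  primers <- primer_binding_similarity(primers, obs_pass, flanked_pass)

  candidates <- passing
  candidates <- dplyr::left_join(candidates, fsim$per_locus, by = "locus_id")
  n_pairs <- primers |>
    dplyr::count(.data$locus_id, name = "n_primer_pairs")
  candidates <- dplyr::left_join(candidates, n_pairs, by = "locus_id")
  candidates$n_primer_pairs[is.na(candidates$n_primer_pairs)] <- 0L
  # wide per-sample repeat counts
  if (nrow(candidates) > 0L) {
    wide <- obs_pass |>
      dplyr::mutate(cell = dplyr::case_when(
        .data$status == "FOUND" ~ as.character(.data$repeats),
        .data$status == "AMBIGUOUS" ~ "AMB",
        TRUE ~ NA_character_)) |>
      dplyr::select("locus_id", "sample", "cell") |>
      tidyr::pivot_wider(names_from = "sample", values_from = "cell",
                         names_prefix = "repeats_")
    wide <- wide[, c("locus_id", paste0("repeats_", nonref)), drop = FALSE]
    candidates <- dplyr::left_join(candidates, wide, by = "locus_id")
  } else {
    for (s in nonref) candidates[[paste0("repeats_", s)]] <- character(0)
    candidates$flank_similarity <- double(0)
  }
  seq_map <- setNames(ss$renames$old[ss$renames$sample == ref],
                      ss$renames$new[ss$renames$sample == ref])
  if (!is.null(gene_models)) {
    candidates <- classify_region(candidates, gene_models,
                                  seq_id_map = seq_map)
  }
  candidates <- dplyr::relocate(candidates, "locus_id")
  summary_tbl <- summarize_candidates(candidates)
  log_lines <- c(log_lines,
                 sprintf("%d candidate(s) with >= 1 primer pair",
                         sum(candidates$n_primer_pairs >= 1L)))

  structure(
    list(candidates = candidates, loci = loci, observations = observations,
         flank_identity = fsim$per_sample, primers = primers,
         summary = summary_tbl, flanked = flanked_pass, config = config,
         renames = ss$renames, log = log_lines),
    class = "polyssr_result")
}

config_echo <- function(config) {
  # workers is an execution detail with no effect on results; keeping it out
  # of the log preserves byte-identical outputs across worker counts
  simple <- config[setdiff(names(config), c("thresholds", "constraints",
                                            "workers"))]
  simple <- simple[!vapply(simple, is.list, logical(1))]
  c(vapply(names(simple), function(k) {
    sprintf("config %s = %s", k, paste(simple[[k]], collapse = ","))
  }, character(1)),
  sprintf("config thresholds = %s",
          paste(names(config$thresholds), unlist(config$thresholds),
                sep = ":", collapse = " ")),
  sprintf("config constraints = %s",
          paste(names(config$constraints), unlist(config$constraints),
                sep = ":", collapse = " ")))
}

#' Run the pipeline from FASTA files
#'
#' Convenience wrapper reading the reference and sample FASTA files (and an
#' optional GFF3 annotation), running [polyssr_run()] and, when `out_dir` is
#' given, writing the output files via [write_outputs()].
#'
#' @param reference Path to the reference FASTA.
#' @param sample_paths Named character vector of non-reference FASTA paths
#'   (names are sample labels).
#' @param reference_label Label for the reference sample (default "REF").
#' @param gff Optional GFF3 path.
#' @param out_dir Optional output directory.
#' @param ... Passed to [polyssr_run()].
#' @return The `polyssr_result` (invisibly when `out_dir` is given).
#' @export
polyssr_run_files <- function(reference, sample_paths,
                              reference_label = "REF", gff = NULL,
                              out_dir = NULL, ...) {
  if (is.null(names(sample_paths)) || any(names(sample_paths) == "")) {
    stop("`sample_paths` must be named by sample label")
  }
  seqs <- c(setNames(list(read_fasta(reference, reference_label)),
                     reference_label),
            lapply(setNames(names(sample_paths), names(sample_paths)),
                   function(s) read_fasta(sample_paths[[s]], s)))
  ss <- sample_set(seqs, reference = reference_label)
  gm <- if (!is.null(gff)) read_gff_genes(gff) else NULL
  res <- polyssr_run(ss, gene_models = gm, ...)
  if (!is.null(out_dir)) {
    write_outputs(res, out_dir)
    return(invisible(res))
  }
  res
}

#' @export
print.polyssr_result <- function(x, ...) {
  cat("<polyssr_result>\n")
  cat("  reference:", x$config$reference, "| samples:",
      paste(setdiff(x$config$samples, x$config$reference), collapse = ", "),
      "\n")
  cat("  ", nrow(x$loci), " reference SSR loci, ", nrow(x$candidates),
      " candidate PolySSRs\n", sep = "")
  if (nrow(x$candidates) > 0L) {
    cat("  mean flank similarity: ",
        sprintf("%.4f", mean(x$candidates$flank_similarity, na.rm = TRUE)),
        "; ", sum(x$candidates$n_primer_pairs >= 1L),
        " with >= 1 primer pair\n", sep = "")
  }
  invisible(x)
}
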