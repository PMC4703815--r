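#' Classify SSR loci by genomic region
#'
#' Assigns each locus exactly one label from CDS, five_prime_UTR,
#' three_prime_UTR, intron, intergenic, judged at the midpoint of the SSR
#' tract with precedence CDS > five_prime_UTR > three_prime_UTR > intron.
#' "Intron" means inside a gene interval but in no CDS/UTR interval of that
#' annotation; a midpoint overlapping no gene (or an absent annotation) is
#' intergenic. UTRs are taken only from explicit UTR features, never inferred.
#'
#' @param loci Locus tibble (`seq_id`, `start`, `end`, 0-based half-open).
#' @param gene_models Tibble from [read_gff_genes()], or `NULL`.
#' @param seq_id_map Optional named character vector translating locus
#'   seq_ids to annotation seq_ids (e.g. stripping the sample prefix added by
#'   [sanitize_headers()]).
#' @return `loci` with a `region` column.
#' @export
classify_region <- function(loci, gene_models = NULL, seq_id_map = NULL) {
  if (nrow(loci) == 0L) {
    loci$region <- character(0)
    return(loci)
  }
  if (is.null(gene_models) || nrow(gene_models) == 0L) {
    loci$region <- "intergenic"
    return(loci)
  }
  sid <- if (is.null(seq_id_map)) loci$seq_id else {
    unname(ifelse(loci$seq_id %in% names(seq_id_map),
                  seq_id_map[loci$seq_id], loci$seq_id))
  }
  mid <- loci$start + (loci$end - loci$start) %/% 2L
  precedence <- c("CDS", "five_prime_UTR", "three_prime_UTR")
  region <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    f <- gene_models[gene_models$seq_id == sid[i] &
                       gene_models$start <= mid[i] &
                       gene_models$end > mid[i], , drop = FALSE]
    hit <- precedence[precedence %in% f$type]
    region[i] <- if (length(hit) > 0L) {
      hit[1L]
    } else if ("gene" %in% f$type) {
      "intron"
    } else {
      "intergenic"
    }
  }
  loci$region <- region
  loci
}

#' Summary statistics over candidate PolySSRs
#'
#' Tabulates candidates by motif-length class (DNR/TNR/TTR/PNR/HNR) and by
#' canonical motif class, summarises the flank-similarity distribution and
#' the fraction of candidates with at least one designed primer pair. Counts
#' are ordered by descending count, then label; percentages are exact
#' fractions of the reported total (rendered `NA` for an empty candidate
#' set). Permutation-invariant in its input.
#'
#' @param candidates Candidate table from [polyssr_run()] (needs `ssr_type`,
#'   `motif_class`, `flank_similarity`, `n_primer_pairs`; a `region` column
#'   is tabulated when present).
#' @return A tibble with columns `section`, `label`, `n`, `value`:
#'   count sections carry counts and percentages, the `statistic` section
#'   carries scalar values (similarity mean/quartiles, primer design rate).
#' @export
summarize_candidates <- function(candidates) {
  total <- nrow(candidates)
  count_section <- function(values, section) {
    if (total == 0L) {
      return(tibble::tibble(section = character(), label = character(),
                            n = integer(), value = double()))
    }
    tab <- table(values)
    out <- tibble::tibble(section = section, label = names(tab),
                          n = as.integer(tab),
                          value = 100 * as.integer(tab) / total)
    dplyr::arrange(out, dplyr::desc(.data$n), .data$label)
  }
  sections <- list(
    tibble::tibble(section = "total", label = "candidates", n = total,
                   value = NA_real_),
    count_section(candidates$ssr_type, "ssr_type"),
    count_section(candidates$motif_class, "motif_class"))
  if ("region" %in% names(candidates)) {
    sections <- c(sections, list(count_section(candidates$region, "region")))
  }
  stats <- if (total > 0L) {
    fs <- candidates$flank_similarity
    qs <- quantile(fs, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, names = FALSE)
    tibble::tibble(
      section = "statistic",
      label = c("mean_flank_similarity", "q0_flank_similarity",
                "q25_flank_similarity", "median_flank_similarity",
                "q75_flank_similarity", "q100_flank_similarity",
                "primer_design_rate_percent"),
      n = NA_integer_,
      value = c(mean(fs, na.rm = TRUE), qs,
                100 * mean(candidates$n_primer_pairs >= 1L)))
  } else {
    tibble::tibble(section = "statistic",
                   label = c("mean_flank_similarity",
                             "primer_design_rate_percent"),
                   n = NA_integer_, value = NA_real_)
  }
  dplyr::bind_rows(c(sections, list(stats)))
}
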