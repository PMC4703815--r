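#' Bar chart of candidate counts by motif class
#'
#' @param result A `polyssr_result`.
#' @param by Count by `"motif_class"` or `"ssr_type"`.
#' @return A ggplot object.
#' @export
plot_motif_classes <- function(result, by = c("motif_class", "ssr_type")) {
  by <- match.arg(by)
  cand <- result$candidates
  if (nrow(cand) == 0L) stop("no candidates to plot")
  counts <- dplyr::count(cand, .data[[by]], sort = TRUE)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = stats::reorder(.data[[by]], -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = by, y = "candidate PolySSRs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of flanking-sequence similarity
#'
#' @param result A `polyssr_result`.
#' @param binwidth Histogram bin width (similarity units).
#' @return A ggplot object.
#' @export
plot_flank_similarity <- function(result, binwidth = 0.005) {
  cand <- result$candidates
  if (nrow(cand) == 0L) stop("no candidates to plot")
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$flank_similarity)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "mean flank similarity", y = "candidate PolySSRs") +
    ggplot2::theme_minimal()
}

#' Autoplot method for pipeline results
#'
#' @param object A `polyssr_result`.
#' @param type One of `"motif_class"`, `"ssr_type"`, `"similarity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.polyssr_result <- function(object,
                                    type = c("motif_class", "ssr_type",
                                             "similarity"), ...) {
  type <- match.arg(type)
  switch(type,
         motif_class = plot_motif_classes(object, "motif_class"),
         ssr_type = plot_motif_classes(object, "ssr_type"),
         similarity = plot_flank_similarity(object))
}

#' @export
ggplot2::autoplot
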