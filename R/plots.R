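#' Plot triplex hits along the genome
#'
#' One point per hit at its start coordinate, coloured by class, separated by
#' strand, sized by stem length.
#'
#' @param object A `triplex_hits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triplex_hits <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$strand,
                                   colour = .data$class,
                                   size = .data$stem_len)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$record_id), ncol = 1L) +
    ggplot2::scale_size_continuous(range = c(1, 3)) +
    ggplot2::labs(x = "position (nt)", y = "strand",
                  colour = "class", size = "stem (nt)",
                  title = "Intrastrand triplex motifs") +
    ggplot2::theme_minimal()
}

#' Plot a variability profile with called regions
#'
#' The windowed variability `v` per alignment column, with the opening and
#' closing thresholds and, when supplied, the called variable regions shaded.
#'
#' @param object A `variability_profile` tibble.
#' @param regions Optional region tibble from [detect_variable_regions()].
#' @param start_threshold,end_threshold Thresholds to draw (defaults 0.9 and
#'   0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.variability_profile <- function(object, regions = NULL,
                                         start_threshold = 0.9,
                                         end_threshold = 0.5, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$v))
  if (!is.null(regions) && nrow(regions) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "gold", alpha = 0.3,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = start_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = end_threshold, linetype = "dotted",
                        colour = "steelblue") +
    ggplot2::labs(x = "alignment column", y = "variability v",
                  title = "Alignment column variability") +
    ggplot2::theme_minimal()
}

#' Plot a wild-type vs scrambled stem-size comparison
#'
#' Side-by-side stem-size histograms of the wild-type genome and its
#' mononucleotide-scrambled control.
#'
#' @param object A `triplex_comparison` object
#'   ([compare_wt_scrambled()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triplex_comparison <- function(object, ...) {
  long <- tidy.triplex_comparison(object)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$stem_len), y = .data$n,
                                     fill = .data$sequence)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "stem size (nt)", y = "hits", fill = NULL,
                  title = "Triplex hits: wild type vs scrambled control") +
    ggplot2::theme_minimal()
}
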