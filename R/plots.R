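#' Bar chart of event-type counts
#'
#' @param events Event catalog from [detect_events()].
#' @return A ggplot object.
#' @export
plot_event_types <- function(events) {
  counts <- dplyr::count(events, .data$event_type)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$event_type, -.data$n), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "AS event type", y = "events",
                  title = "Alternative-splicing events by type") +
    ggplot2::theme_minimal()
}

#' Intron length distribution
#'
#' Log10 histogram of intron lengths with the 50 kb "enormous" threshold
#' marked.
#'
#' @param features Intron table with a `length` column.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_intron_lengths <- function(features, bins = 50) {
  ggplot2::ggplot(features, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = 50000, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "intron length (nt, log scale)", y = "introns",
                  title = "Intron length distribution") +
    ggplot2::theme_minimal()
}

#' Border dinucleotide composition
#'
#' @param features Output of [border_dinucleotides()] /
#'   [intron_features()].
#' @param top Number of border classes to show.
#' @return A ggplot object.
#' @export
plot_border_dinucleotides <- function(features, top = 5) {
  counts <- features %>%
    dplyr::count(.data$border, sort = TRUE) %>%
    dplyr::slice_head(n = top) %>%
    dplyr::mutate(frac = .data$n / sum(.data$n))
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$border, -.data$n), y = .data$frac)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "intron border", y = "fraction of introns",
                  title = "Intron border dinucleotides") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential-splicing fit
#'
#' Delta PSI between the two conditions against -log10 q-value.
#'
#' @param object A `splice_diff` object from [differential_splicing()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_diff <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_psi,
                                  y = -log10(.data$q_value),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * PSI), y = expression(-log[10](q)),
                  title = sprintf("Differential splicing: %s vs %s",
                                  object$comparison[1],
                                  object$comparison[2])) +
    ggplot2::theme_minimal()
}
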