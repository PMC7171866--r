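#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of assembly-process fractions
#'
#' The classic stacked-process figure: percentage of community pairs
#' attributed to each ecological process.
#'
#' @param object A `process_summary` (or an `assembly_quantification`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.process_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$process, y = 100 * .data$fraction,
                                       fill = .data$process)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of community pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.assembly_quantification <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' Mantel correlogram plot
#'
#' Mantel r per distance class; filled points mark classes significant
#' after progressive correction (p < 0.05).
#'
#' @param object A `mantel_correlogram` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mantel_correlogram <- function(object, ...) {
  df <- object[!is.na(object$mantel_r), ]
  df$significant <- !is.na(df$p_corrected) & df$p_corrected < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_midpoint, y = .data$mantel_r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant), shape = 22, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               name = "p < 0.05") +
    ggplot2::labs(x = "Distance class midpoint", y = "Mantel r") +
    ggplot2::theme_minimal()
}

#' Sequential beta-diversity along the cruise track
#'
#' Dissimilarity of each station to its predecessor, with abrupt changes
#' highlighted.
#'
#' @param object A `sequential_beta` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sequential_beta <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cruise_order, y = .data$dissimilarity)) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$abrupt, size = .data$dissimilarity)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "grey30"),
                                 name = paste0("> ", thr)) +
    ggplot2::guides(size = "none") +
    ggplot2::labs(x = "Cruise order", y = "Dissimilarity to predecessor") +
    ggplot2::theme_minimal()
}

#' LCBD per station
#'
#' @param object An `lcbd_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lcbd_result <- function(object, ...) {
  df <- object
  df$significant <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$lcbd,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 / nrow(df), linetype = 2, colour = "grey50") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#B2182B", `FALSE` = "grey60"),
                               name = "p < 0.05") +
    ggplot2::labs(x = NULL, y = "LCBD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom rlang .data
NULL
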