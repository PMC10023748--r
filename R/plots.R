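# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a correction result
#'
#' Corrected vs baseline turnover numbers on log10 axes; points above the
#' identity line are corrected enzymes.
#'
#' @param object a `correction_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.correction_result <- function(object, ...) {
  stopifnot(object$status == "optimal")
  d <- object$delta
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kcat_min, y = .data$kcat_new)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$delta > 1e-6)) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 name = "corrected") +
    ggplot2::labs(x = "initial kcat (s^-1)", y = "corrected kcat (s^-1)") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation report
#'
#' Mean validation error and mean total correction along the lambda grid,
#' with the selected lambda marked.
#'
#' @param object a `cv_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cv_report <- function(object, ...) {
  m <- object$measures |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(omega = mean(.data$omega, na.rm = TRUE),
                     Delta = mean(.data$Delta, na.rm = TRUE)) |>
    tidyr::pivot_longer(c("omega", "Delta"), names_to = "measure")
  ggplot2::ggplot(m, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda_opt, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "lambda",
                  y = "mean validation error / total correction") +
    ggplot2::theme_minimal()
}

#' Plot variability intervals
#'
#' Per-enzyme correction intervals at the fixed optimum, with the fitted
#' correction marked.
#'
#' @param object a `variability_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variability_result <- function(object, ...) {
  d <- object$intervals
  ggplot2::ggplot(d, ggplot2::aes(y = stats::reorder(.data$enzyme,
                                                     .data$delta_opt))) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$delta_min,
                                         xmax = .data$delta_max)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$delta_opt),
                        colour = "firebrick") +
    ggplot2::labs(x = "correction delta (s^-1)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Corrected-enzyme counts per pathway term, shaded by adjusted q-value.
#'
#' @param object an `enrichment_table`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x,
                               y = stats::reorder(.data$term, -.data$q),
                               fill = .data$q)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "grey70") +
    ggplot2::labs(x = "corrected enzymes", y = NULL, fill = "BH q") +
    ggplot2::theme_minimal()
}
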