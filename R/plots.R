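#' Plot methods
#'
#' `autoplot()` methods for the main result types: the state trace (stacked
#' occupancy areas), the PSA cloud on the cost-effectiveness plane, the
#' cost-effectiveness acceptability curve and the tornado diagram.
#'
#' @param object A `petvoi_trace`, `petvoi_psa`, `petvoi_ceac` or
#'   `petvoi_tornado` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name petvoi-plots
NULL

#' @rdname petvoi-plots
#' @exportS3Method ggplot2::autoplot
autoplot.petvoi_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("time", "stable", "progressed_local", "metastatic", "dead")],
    -"time", names_to = "state", values_to = "occupancy")
  long$state <- factor(long$state,
                       c("dead", "metastatic", "progressed_local", "stable"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$occupancy,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Time (years)", y = "State occupancy",
                  title = paste("State trace:", attr(object, "strategy"))) +
    ggplot2::theme_minimal()
}

#' @rdname petvoi-plots
#' @exportS3Method ggplot2::autoplot
autoplot.petvoi_psa <- function(object, ...) {
  wide <- tidyr::pivot_wider(object$draws, id_cols = "iteration",
                             names_from = "strategy",
                             values_from = c("cost", "qaly"))
  df <- tibble::tibble(
    d_qaly = wide$qaly_surgery_et - wide$qaly_pet,
    d_cost = wide$cost_surgery_et - wide$cost_pet)
  ggplot2::ggplot(df, ggplot2::aes(.data$d_qaly, .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 20000, intercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "Cost-effectiveness plane (surgery + ET vs PET)") +
    ggplot2::theme_minimal()
}

#' @rdname petvoi-plots
#' @exportS3Method ggplot2::autoplot
autoplot.petvoi_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$probability,
                                       colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' @rdname petvoi-plots
#' @exportS3Method ggplot2::autoplot
autoplot.petvoi_tornado <- function(object, ...) {
  df <- dplyr::mutate(object,
                      parameter = factor(.data$parameter,
                                         rev(.data$parameter)))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low,
                                       xend = .data$inmb_high,
                                       y = .data$parameter,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$inmb_base),
                        linetype = 2) +
    ggplot2::labs(x = sprintf("INMB at GBP %s per QALY",
                              format(attr(object, "threshold"),
                                     big.mark = ",")),
                  y = NULL, title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}
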