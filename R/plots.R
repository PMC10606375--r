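# ggplot2 views of the main result types.

#' Plot a simulated Franz-cell run
#'
#' Cumulative receptor amount per area over time, with the per-compartment
#' group amounts as an optional second panel quantity.
#'
#' @param object a `franz_simulation`.
#' @param what `"cumulative"` (default) or `"compartments"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.franz_simulation <- function(object,
                                      what = c("cumulative", "compartments"),
                                      ...) {
  what <- match.arg(what)
  if (what == "cumulative") {
    q <- cumulative_per_area(object)
    ggplot2::ggplot(q, ggplot2::aes(x = .data$time_h,
                                    y = .data$q_ug_per_cm2)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = "time (h)",
                    y = expression("cumulative amount (" * mu * g / cm^2 * ")"),
                    title = sprintf("virtual %s", toupper(object$mode))) +
      ggplot2::theme_minimal()
  } else {
    df <- as_tibble(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$amount_ug,
                                     colour = .data$group)) +
      ggplot2::geom_line(linewidth = 0.7) +
      ggplot2::labs(x = "time (h)", y = expression("amount (" * mu * g * ")"),
                    colour = "compartment") +
      ggplot2::theme_minimal()
  }
}

#' Plot a replicate dataset
#'
#' Replicate cumulative-permeation curves with the replicate mean
#' highlighted.
#'
#' @param object a `franz_dataset`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.franz_dataset <- function(object, ...) {
  p <- object$permeation
  m <- dplyr::summarise(dplyr::group_by(p, .data$time_h),
                        q_ug_per_cm2 = mean(.data$q_ug_per_cm2),
                        .groups = "drop")
  ggplot2::ggplot(p, ggplot2::aes(x = .data$time_h, y = .data$q_ug_per_cm2)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                       alpha = 0.35, linewidth = 0.4) +
    ggplot2::geom_line(data = m, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "time (h)",
                  y = expression("cumulative amount (" * mu * g / cm^2 * ")"),
                  title = object$group) +
    ggplot2::theme_minimal()
}

#' Plot a calibration fit
#'
#' Observed mean profile against the simulated profile at the optimum, plus
#' the best-so-far objective trace.
#'
#' @param object a `calibration_result`.
#' @param what `"fit"` (default) or `"trace"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.calibration_result <- function(object, what = c("fit", "trace"),
                                        ...) {
  what <- match.arg(what)
  if (what == "fit") {
    r <- object$residuals
    df <- tidyr::pivot_longer(r, c("observed", "simulated"),
                              names_to = "series", values_to = "q")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$q,
                                     colour = .data$series)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::geom_point(size = 1.4) +
      ggplot2::labs(x = "time (h)",
                    y = expression("cumulative amount (" * mu * g / cm^2 * ")"),
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$trace,
                    ggplot2::aes(x = .data$eval, y = .data$best_so_far)) +
      ggplot2::geom_step(linewidth = 0.7) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "objective evaluation", y = "best objective so far") +
      ggplot2::theme_minimal()
  }
}
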