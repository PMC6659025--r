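#' Plot a growth trajectory
#'
#' Weight-at-age with the maturation point (50% allocation to reproduction)
#' marked, plus optional panels for activity, allocation and survival.
#'
#' @param object A `fin_trajectory` from [grow()].
#' @param vars Columns to facet over (default weight, activity, allocation,
#'   survival).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fin_trajectory <- function(object,
                                    vars = c("w", "tau_star", "psi", "S"),
                                    ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("t", vars)],
                            cols = -"t", names_to = "variable")
  df$variable <- factor(df$variable, levels = vars)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "age (y)", y = NULL,
                  title = sprintf("T = %.1f C, food x %.2f",
                                  attr(object, "T"), attr(object, "food")))
  mat <- attr(object, "maturation_age")
  if (!is.na(mat)) {
    gg <- gg + ggplot2::geom_vline(xintercept = mat, linetype = "dotted")
  }
  gg
}

#' Plot a thermal-response sweep
#'
#' One line per metric against temperature, faceted by strategy and MOS
#' regime, for a chosen size and food level -- the classic shape of
#' thermal-performance panels.
#'
#' @param object A `scenario_result` from [run_sweep()].
#' @param w Which diagnostic size to show (default: the smallest present).
#' @param food Which food multiplier to show (default: closest to 1).
#' @param metrics Metric columns to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_result <- function(object, w = NULL, food = NULL,
                                     metrics = c("f", "P_rel", "M_rel",
                                                 "PM_rel", "efficiency"),
                                     ...) {
  w <- w %||% min(object$w)
  food <- food %||% object$food_multiplier[
    which.min(abs(object$food_multiplier - 1))]
  df <- dplyr::filter(as_tibble(object), .data$w == !!w,
                      abs(.data$food_multiplier - !!food) < 1e-9)
  df <- tidyr::pivot_longer(df[, c("strategy", "mos_regime", "T", metrics)],
                            cols = dplyr::all_of(metrics),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$T, y = .data$value,
                                   color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(mos_regime ~ strategy) +
    ggplot2::labs(x = "temperature (C)", y = NULL,
                  title = sprintf("w = %g g, food x %.2f", w, food))
}
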