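#' Plot a simulated trajectory
#'
#' Lines for each state variable against time; counts are drawn on a log
#' scale by default because both plant and beetle dynamics are close to
#' exponential.
#'
#' @param traj A trajectory tibble from [simulate_plant()] or
#'   [integrate_model()].
#' @param vars Columns to draw (default: every column except `time` and
#'   `rep`).
#' @param log_y Use a log10 y-axis (zero counts are dropped).
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, vars = NULL, log_y = TRUE) {
  vars <- vars %||% setdiff(names(traj), c("time", "rep"))
  long <- tidyr::pivot_longer(traj, dplyr::all_of(vars),
                              names_to = "variable", values_to = "count")
  if (log_y) long <- dplyr::filter(long, .data$count > 0)
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$count,
                                          colour = .data$variable)) +
    ggplot2::labs(x = "time (days)", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
  p <- if ("rep" %in% names(traj)) {
    p + ggplot2::geom_line(ggplot2::aes(group = interaction(.data$rep,
                                                            .data$variable)),
                           alpha = 0.3)
  } else {
    p + ggplot2::geom_line()
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a damage map
#'
#' Tile map of relative leaf damage over stand size and release size,
#' with the critical-release-size curve overlaid when available.
#'
#' @param dm Output of [damage_map()].
#' @return A ggplot object.
#' @export
plot_damage_map <- function(dm) {
  p <- ggplot2::ggplot(dm, ggplot2::aes(factor(.data$P0), factor(.data$B0),
                                        fill = .data$damage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "initial nodes P0", y = "adults released B0",
                  fill = "damage") +
    ggplot2::theme_minimal()
  thr <- attr(dm, "threshold")
  if (!is.null(thr)) {
    p <- p + ggplot2::geom_line(
      data = thr,
      ggplot2::aes(factor(.data$P0), .data$B0_star, group = 1),
      inherit.aes = FALSE, linetype = "dashed", colour = "white"
    )
  }
  p
}

#' Plot sensitivity effect sizes
#'
#' Point-and-interval display of the regression coefficients (one per
#' scaled parameter); the intercept is dropped.
#'
#' @param fit A `"sensitivity_fit"` from [sensitivity_regression()].
#' @param conf_mult Half-width of the interval in standard errors.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(fit, conf_mult = 2) {
  td <- dplyr::filter(tidy(fit), .data$term != "(Intercept)")
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate,
                                   stats::reorder(.data$term,
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - conf_mult * .data$std.error,
                   xmax = .data$estimate + conf_mult * .data$std.error)
    ) +
    ggplot2::labs(x = "effect on critical release size (per 100 leaves)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
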