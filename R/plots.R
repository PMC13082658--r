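#' Plot an optimal-control solution
#'
#' Four stacked panels over time: joint angle (with the target), joint
#' velocity, activations and excitations (flexor positive, extensor shown
#' negative, the usual antagonist-pair convention).
#'
#' @param object An `ocp_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocp_solution <- function(object, ...) {
  tr <- object$trajectory
  target_deg <- 180 / pi * object$task$theta_target
  df <- dplyr::bind_rows(
    tibble::tibble(time = tr$time, panel = "angle (deg)",
                   series = "theta", value = 180 / pi * tr$theta),
    tibble::tibble(time = tr$time, panel = "velocity (rad/s)",
                   series = "omega", value = tr$omega),
    tibble::tibble(time = tr$time, panel = "activation",
                   series = "flexor", value = tr$a_flex),
    tibble::tibble(time = tr$time, panel = "activation",
                   series = "extensor", value = -tr$a_ext),
    tibble::tibble(time = tr$time, panel = "excitation",
                   series = "flexor", value = tr$u_flex),
    tibble::tibble(time = tr$time, panel = "excitation",
                   series = "extensor", value = -tr$u_ext)
  )
  df$panel <- factor(df$panel, c("angle (deg)", "velocity (rad/s)",
                                 "activation", "excitation"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$panel == "excitation"),
                       na.rm = TRUE) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$panel != "excitation"),
                       na.rm = TRUE) +
    ggplot2::geom_hline(
      data = data.frame(panel = factor("angle (deg)",
                                       levels = levels(df$panel)),
                        y = target_deg),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot importance coefficients
#'
#' Bar chart of the importance-regression coefficients, with the
#' first-order importance threshold (magnitude 0.1) marked.
#'
#' @param object An `importance_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_fit <- function(object, ...) {
  df <- object$coefficients
  df$term <- factor(df$term, rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = 3) +
    ggplot2::labs(x = "importance (normalised coefficient)", y = NULL,
                  subtitle = sprintf("%s, R² = %.3f",
                                     object$variant, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Performance landscape over a parameter plane
#'
#' Filled tile-and-contour map of a sweep metric over two parameter
#' columns of a sweep table (e.g. the deactivation-time x stiffness
#' plane).
#'
#' @param table A sweep table from [run_sweep()].
#' @param x,y Parameter column names.
#' @param fill Metric column name (default `"J_RMSE"`).
#' @return A ggplot object.
#' @export
plot_sweep_plane <- function(table, x = "alpha_d", y = "c1",
                             fill = "J_RMSE") {
  ggplot2::ggplot(table, ggplot2::aes(.data[[x]], .data[[y]],
                                      fill = .data[[fill]],
                                      z = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_contour(colour = "white", bins = 10) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = x, y = y, fill = fill) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
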