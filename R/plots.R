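#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_point geom_step geom_ribbon labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' Plot a kymograph
#'
#' @param object A [as_kymograph()] object.
#' @param ... Unused.
#' @return A ggplot: time vs position, intensity as fill.
#' @export
autoplot.kymograph <- function(object, ...) {
  as_tibble(object) |>
    ggplot(aes(x = .data$position_nt / 1000, y = .data$time_s, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(name = "a.u.") +
    labs(x = "Position (knt)", y = "Time (s)",
         title = sprintf("Kymograph (%s)", object$channel)) +
    theme_minimal()
}

#' Plot a binned velocity distribution with its Gaussian fit
#'
#' @param object A `velocity_fit`.
#' @param ... Unused.
#' @return A ggplot of histogram counts and the fitted Gaussian.
#' @export
autoplot.velocity_fit <- function(object, ...) {
  grid <- tibble(
    mid = seq(0, max(object$bins$mid) * 1.1, length.out = 200)
  ) |>
    mutate(fitted = object$amplitude * exp(-(.data$mid - object$mu)^2 / (2 * object$sigma^2)))
  ggplot(object$bins, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = object$bin_width * 0.9, fill = "grey70") +
    geom_line(data = grid, aes(y = .data$fitted), colour = "#2166ac", linewidth = 1) +
    labs(
      x = "Velocity (nt/s)", y = "Count",
      title = sprintf("%.0f +/- %.0f nt/s (N = %d)", object$mu, object$sigma, object$n)
    ) +
    theme_minimal()
}

#' Plot a survival curve with its exponential fit
#'
#' @param object A `survival_fit`.
#' @param ... Unused.
#' @return A ggplot of the empirical survival and fitted decay.
#' @export
autoplot.survival_fit <- function(object, ...) {
  grid <- tibble(distance_nt = seq(0, max(object$curve$distance_nt), length.out = 200)) |>
    mutate(fitted = exp(-object$lambda * pmax(.data$distance_nt - object$d_min, 0)))
  ggplot(object$curve, aes(x = .data$distance_nt / 1000, y = .data$survival)) +
    geom_step() +
    geom_line(data = grid, aes(y = .data$fitted), colour = "#b2182b") +
    labs(
      x = "Distance (knt)", y = "Survival probability",
      title = sprintf("Half-life %.0f nt (95%% CI %.0f-%.0f)",
                      object$half_life, object$ci[1], object$ci[2])
    ) +
    theme_minimal()
}

#' Plot an intensity trace fit
#'
#' @param object A `rate_fit`.
#' @param ... Unused.
#' @return A ggplot of data and fitted exponential.
#' @export
autoplot.rate_fit <- function(object, ...) {
  ggplot(object$fitted, aes(x = .data$time_s)) +
    geom_point(aes(y = .data$intensity), size = 0.6, alpha = 0.6) +
    geom_line(aes(y = .data$fitted), colour = "#2166ac") +
    labs(x = "Time (s)", y = "Normalised intensity",
         title = sprintf("%s: k = %.3g 1/s", object$model, object$k)) +
    theme_minimal()
}

#' Plot a step-fit over its photobleaching trace
#'
#' @param object A `step_calls`.
#' @param ... Unused.
#' @return A ggplot of the trace and the fitted piecewise-constant levels.
#' @export
autoplot.step_calls <- function(object, ...) {
  tr <- object$trace
  lev <- object$levels |>
    mutate(start_s = tr$time_s[.data$start_idx], end_s = tr$time_s[.data$end_idx])
  ggplot(tr, aes(x = .data$time_s, y = .data$intensity)) +
    geom_line(colour = "grey60") +
    ggplot2::geom_segment(
      data = lev,
      aes(x = .data$start_s, xend = .data$end_s, y = .data$level, yend = .data$level),
      colour = "#b2182b", linewidth = 1
    ) +
    labs(x = "Time (s)", y = "Intensity (a.u.)",
         title = sprintf("%d bleaching step(s)", object$n_steps)) +
    theme_minimal()
}
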