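#' Plot an organelle time course, optionally with model fit curves
#'
#' Points with mean +/- s.d. error bars per organelle; when a `flux_fit`
#' is supplied its smooth model solution is overlaid. The time axis is
#' log-scaled (pseudo-log: the 0 min point is kept) because the sampling
#' spans minutes to a day.
#'
#' @param timecourse Tibble with `time_min`, `organelle`, `mean`, `sd`.
#' @param fit Optional `flux_fit`.
#' @param n_curve Points per fitted curve, default 200.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse, fit = NULL, n_curve = 200) {
  tc <- tibble::as_tibble(timecourse)
  tc$organelle <- normalize_organelle(tc$organelle)
  p <- ggplot2::ggplot(tc, ggplot2::aes(
    x = .data$time_min + 1, y = .data$mean, colour = .data$organelle
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.05
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time + 1 (min, log scale)", y = "lipid fraction",
                  colour = "organelle") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "flux_fit"))
    tmax <- max(tc$time_min)
    times <- unique(c(0, exp(seq(log(1), log(tmax + 1),
                                 length.out = n_curve)) - 1))
    traj <- simulate_flux(fit$model, fit$point_estimate, fit$x0,
                          sort(times),
                          content_decay_rate = fit$content_decay_rate,
                          force_decay = fit$content_decay_rate > 0)
    p <- p + ggplot2::geom_line(
      data = traj,
      ggplot2::aes(x = .data$time_min + 1, y = .data$fraction,
                   colour = .data$organelle)
    )
  }
  p
}

#' @describeIn plot_timecourse autoplot method for fitted models: the data
#'   the model was fitted to with the fitted curves overlaid.
#' @param object A `flux_fit`.
#' @param ... Unused.
#' @export
autoplot.flux_fit <- function(object, ...) {
  plot_timecourse(object$data, fit = object)
}

#' Plot Monte Carlo rate-constant distributions
#'
#' One panel per rate constant showing the spread of the MC estimates; the
#' point estimate is marked by a vertical line.
#'
#' @param fit A `flux_fit` with MC samples.
#' @param bins Histogram bins, default 20.
#' @return A ggplot object.
#' @export
plot_mc_rates <- function(fit, bins = 20) {
  stopifnot(inherits(fit, "flux_fit"))
  if (is.null(fit$mc_samples)) abort("Fit carries no MC samples.")
  long <- tibble::as_tibble(as.data.frame(fit$mc_samples)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "rate", values_to = "estimate")
  pts <- tibble::tibble(rate = names(fit$point_estimate),
                        estimate = unname(fit$point_estimate))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = pts,
                        ggplot2::aes(xintercept = .data$estimate),
                        colour = "firebrick") +
    ggplot2::facet_wrap(~rate, scales = "free") +
    ggplot2::labs(x = expression(rate ~ constant ~ (min^-1)), y = "MC runs") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.partition_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$organelle, y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of assigned lipid signal") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.metabolism_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_min,
                                        y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (min)", y = "supplied fraction of BF lipidome") +
    ggplot2::theme_minimal()
  if (isTRUE(object$fitted)) {
    tt <- seq(min(df$time_min), max(df$time_min), length.out = 200)
    curve <- tibble::tibble(
      time_min = tt,
      fraction = object$f0 * exp(-object$k_met * tt)
    )
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  } else if (!is.null(object$interpolate)) {
    tt <- seq(min(df$time_min), max(df$time_min), length.out = 200)
    curve <- tibble::tibble(time_min = tt, fraction = object$interpolate(tt))
    p <- p + ggplot2::geom_line(data = curve, colour = "grey40",
                                linetype = "dashed")
  }
  p
}
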