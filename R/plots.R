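#' Diagnostic plot for a maximum-likelihood fit
#'
#' Histogram of the data overlaid with the fitted density, side by side
#' with the empirical survival curve and the fitted survival function.
#'
#' @param object An `esw_fit` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esw_fit <- function(object, bins = 20, ...) {
  x <- object$data
  cdf <- fitted_cdf(object)
  grid <- seq(min(x) * 0.8, max(x) * 1.05, length.out = 200)
  th <- object$theta_full
  dens <- if (object$model == "weibull") {
    th[3] * th[2] * grid^(th[2] - 1) * exp(-th[3] * grid^th[2])
  } else {
    desw(grid, th[1], th[2], th[3])
  }
  df_curve <- tibble::tibble(x = grid, pdf = dens, sf = 1 - cdf(grid))
  xs <- sort(x)
  df_emp <- tibble::tibble(x = xs,
                           sf = 1 - seq_along(xs) / length(xs))
  p1 <- ggplot2::ggplot(tibble::tibble(x = x), ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "white") +
    ggplot2::geom_line(data = df_curve,
                       ggplot2::aes(x = .data$x, y = .data$pdf),
                       colour = "red") +
    ggplot2::labs(x = "x", y = "density") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(df_emp, ggplot2::aes(x = .data$x, y = .data$sf)) +
    ggplot2::geom_step() +
    ggplot2::geom_line(data = df_curve, colour = "red") +
    ggplot2::labs(x = "x", y = "survival") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 + p2
  } else {
    p1
  }
}

#' Profile log-likelihood plot
#'
#' @param object A tibble from [esw_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "parameter value", y = "profile log-likelihood") +
    ggplot2::theme_minimal()
}
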