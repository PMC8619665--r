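#' Goodness-of-fit and model-selection report
#'
#' Computes the Kolmogorov-Smirnov, Anderson-Darling and Cramer-von Mises
#' statistics of a sample against a fitted parametric CDF, together with
#' AIC, BIC and the small-sample corrected AIC. Statistics are evaluated
#' with the estimated parameters plugged in (no Lilliefors-style
#' correction), and the KS p-value uses the asymptotic Kolmogorov limit of
#' \eqn{\sqrt{n} D}.
#'
#' @param data Sample vector.
#' @param cdf A function of `x` returning the fitted CDF.
#' @param loglik Maximized log-likelihood of the fitted model.
#' @param k Number of estimated parameters.
#' @return A one-row tibble with columns `ks`, `ks_p`, `ad`, `cvm`, `aic`,
#'   `bic`, `caic`, `n`, `k`.
#' @details With \eqn{u_i} the fitted CDF at the sorted sample,
#'   \eqn{D = \max_i \max(i/n - u_i,\; u_i - (i-1)/n)},
#'   \eqn{A^2 = -n - \frac{1}{n}\sum (2i-1)[\log u_i + \log(1-u_{n+1-i})]},
#'   \eqn{W^2 = \frac{1}{12n} + \sum (u_i - \frac{2i-1}{2n})^2}; the
#'   criteria are \eqn{AIC = -2L + 2k}, \eqn{BIC = -2L + k\log n} and
#'   \eqn{CAIC = AIC + 2k(k+1)/(n-k-1)}. Fitted CDF values that reach 0 or
#'   1 numerically are clamped to \eqn{[10^{-12}, 1-10^{-12}]} with a
#'   warning.
#' @export
gof_report <- function(data, cdf, loglik, k) {
  n <- length(data)
  stopifnot(n >= 1)
  u <- sort(cdf(sort(data)))
  if (any(u <= 0 | u >= 1)) {
    warning("fitted CDF values at 0 or 1 clamped to [1e-12, 1 - 1e-12]")
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  }
  i <- seq_len(n)
  ks <- max(pmax(i / n - u, u - (i - 1) / n))
  ad <- -n - sum((2 * i - 1) * (log(u) + log(1 - rev(u)))) / n
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  aic <- -2 * loglik + 2 * k
  tibble::tibble(
    ks = ks,
    ks_p = ks_pvalue_asymptotic(sqrt(n) * ks),
    ad = ad,
    cvm = cvm,
    aic = aic,
    bic = -2 * loglik + k * log(n),
    caic = aic + 2 * k * (k + 1) / (n - k - 1),
    n = n,
    k = k
  )
}

# asymptotic Kolmogorov distribution: P(sqrt(n) D > t)
ks_pvalue_asymptotic <- function(t) {
  if (t < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

#' Scaled total-time-on-test transform
#'
#' The TTT curve \eqn{T(i/n) = [\sum_{j \le i} x_{(j)} + (n-i) x_{(i)}] /
#' \sum_j x_{(j)}} diagnoses hazard shape: a concave curve indicates an
#' increasing hazard, convex a decreasing one, and an S shape a bathtub.
#'
#' @param data Vector of at least two strictly positive observations.
#' @return A tibble with columns `p` (\eqn{i/n}) and `ttt`; the final value
#'   is always 1.
#' @export
ttt_points <- function(data) {
  check_sample(data)
  n <- length(data)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  xs <- sort(data)
  i <- seq_len(n)
  out <- tibble::tibble(p = i / n,
                        ttt = (cumsum(xs) + (n - i) * xs) / sum(xs))
  class(out) <- c("esg_ttt", class(out))
  out
}

#' @rdname ttt_points
#' @param object A tibble from [ttt_points()].
#' @param ... Unused.
#' @export
autoplot.esg_ttt <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$p, y = .data$ttt)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "i/n", y = "scaled TTT") +
    ggplot2::theme_minimal()
}
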