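#' Integer power of a power series
#'
#' Given the coefficients \eqn{a_0, a_1, \dots} of a power series
#' \eqn{\sum_k a_k x^k} and a positive integer \eqn{n}, returns the
#' coefficients \eqn{c_0, \dots, c_K} of the \eqn{n}-th power of the series,
#' by the classical recursion
#' \deqn{c_0 = a_0^n, \qquad
#'   c_m = \frac{1}{m a_0} \sum_{k=1}^{m} (kn - m + k)\, a_k\, c_{m-k}.}
#'
#' @param a Numeric vector of series coefficients, `a[1]` being the constant
#'   term; must have a nonzero constant term.
#' @param n Positive integer power.
#' @param K Truncation order: coefficients of \eqn{x^0,\dots,x^K} are
#'   returned.
#' @return Numeric vector of length `K + 1`.
#' @examples
#' power_series_pow(c(1, 1), 2, 3)  # (1 + x)^2 = 1 + 2x + x^2
#' @export
power_series_pow <- function(a, n, K) {
  stopifnot(length(a) >= 1L, n >= 1L, n == round(n), K >= 0L)
  if (a[1] == 0) {
    stop("the constant term `a[1]` must be nonzero (the recursion divides ",
         "by it)", call. = FALSE)
  }
  a <- c(a, rep(0, max(0, K + 1L - length(a))))[seq_len(K + 1L)]
  cc <- numeric(K + 1L)
  cc[1] <- a[1]^n
  if (K >= 1L) {
    for (m in seq_len(K)) {
      k <- seq_len(m)
      cc[m + 1L] <- sum((k * n - m + k) * a[k + 1L] * cc[m - k + 1L]) /
        (m * a[1])
    }
  }
  cc
}

#' Alternating series constant of the sine expansion
#'
#' The constant \eqn{A = \sum_{n \ge 1} (-1)^n (\pi/2)^{2n} / (2n+1)!},
#' which equals \eqn{2/\pi - 1 \approx -0.36338}. It bounds the inner series
#' of the sine-power expansion on \eqn{[0,1]} and certifies its convergence.
#'
#' @param tol Stop when a term falls below this magnitude.
#' @return The limiting value of the series.
#' @export
sine_series_constant <- function(tol = 1e-16) {
  s <- 0
  for (n in 1:60) {
    term <- (-1)^n * (pi / 2)^(2 * n) / factorial(2 * n + 1)
    s <- s + term
    if (abs(term) < tol) break
  }
  s
}

# inner sine-expansion coefficients a_i = (-1)^(i+1) (pi/2)^(2i+2) / (2i+3)!
sine_inner_coefs <- function(K) {
  i <- 0:K
  (-1)^(i + 1) * (pi / 2)^(2 * i + 2) / factorial(2 * i + 3)
}

#' Power-series expansion of a sine power
#'
#' Expands \eqn{\sin((\pi/2) G)^w} as a (generally non-integer) power series
#' in \eqn{G}:
#' \deqn{\sin((\pi/2)G)^w = (\pi/2)^w G^w
#'   + \sum_{l \ge 1} \sum_{i \ge 0} \binom{w}{l} (\pi/2)^w\, b_i^{(l)}\,
#'     G^{2(i+l)+w},}
#' where the \eqn{b^{(l)}} follow from [power_series_pow()] applied to the
#' inner sine coefficients. In the ESG density the exponent is
#' \eqn{w = \alpha - 1}; the Renyi-entropy integrand uses
#' \eqn{w = \rho(\alpha-1)}.
#'
#' @param w Real exponent. `w = 0` yields the constant series 1. Positive
#'   integer `w` is rejected: the binomial expansion assumes a noninteger
#'   exponent, and integer powers are evaluated directly instead.
#' @param K Truncation order for both series indices.
#' @return An object of class `esg_series` with a tibble of
#'   `(power, coef)` pairs; evaluate it with [eval_series()].
#' @export
sine_power_series <- function(w, K = 25) {
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  if (w == 0) {
    out <- tibble::tibble(power = 0, coef = 1)
  } else if (w > 0 && w == round(w)) {
    stop("integer exponents are evaluated directly, not by the binomial ",
         "series expansion", call. = FALSE)
  } else {
    a <- sine_inner_coefs(K)
    pieces <- vector("list", K + 1L)
    pieces[[1]] <- tibble::tibble(power = w, coef = (pi / 2)^w)
    for (l in seq_len(K)) {
      b <- power_series_pow(a, l, K)
      i <- 0:K
      pieces[[l + 1L]] <- tibble::tibble(
        power = 2 * (i + l) + w,
        coef = choose(w, l) * (pi / 2)^w * b
      )
    }
    out <- dplyr::bind_rows(pieces)
  }
  structure(list(kind = "sine-power", exponent = w, coefficients = out,
                 truncation_order = K, tolerance = 1e-12),
            class = "esg_series")
}

#' Power-series expansion of a cosine power
#'
#' Expands \eqn{\cos((\pi/2) G)^\rho} as
#' \deqn{\cos((\pi/2)G)^\rho = 1 + \sum_{j \ge 1} \sum_{k \ge 0}
#'   \binom{\rho}{j} z_k^{*(j)}\, G^{2(k+j)},}
#' with \eqn{z_k = (-1)^{k+1} (\pi/2)^{2(k+1)} / (2(k+1))!} and
#' \eqn{z^{*(j)}} its \eqn{j}-th series power.
#'
#' @param rho Positive real exponent (the expansion targets noninteger
#'   exponents; integer `rho` works too since the binomial terminates).
#' @param K Truncation order for both series indices.
#' @return An `esg_series` object; evaluate with [eval_series()].
#' @export
cosine_power_series <- function(rho, K = 25) {
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  check_positive(rho, "rho")
  k <- 0:K
  z <- (-1)^(k + 1) * (pi / 2)^(2 * (k + 1)) / factorial(2 * (k + 1))
  jmax <- if (rho == round(rho)) min(K, rho) else K
  pieces <- vector("list", jmax + 1L)
  pieces[[1]] <- tibble::tibble(power = 0, coef = 1)
  for (j in seq_len(jmax)) {
    zs <- power_series_pow(z, j, K)
    pieces[[j + 1L]] <- tibble::tibble(
      power = 2 * (k + j),
      coef = choose(rho, j) * zs
    )
  }
  structure(list(kind = "cosine-power", exponent = rho,
                 coefficients = dplyr::bind_rows(pieces),
                 truncation_order = K, tolerance = 1e-12),
            class = "esg_series")
}

#' Evaluate a truncated series expansion at baseline CDF values
#'
#' @param series An `esg_series` from [sine_power_series()],
#'   [cosine_power_series()] or [desg_series_coefs()].
#' @param g Vector of baseline CDF values \eqn{G(x)} at which to evaluate.
#'   The expansions are certified on \eqn{G \in [0, 0.9]} only; values above
#'   are refused (convergence near \eqn{G = 1} is too slow to certify at the
#'   stored truncation order).
#' @return Numeric vector of series values.
#' @export
eval_series <- function(series, g) {
  stopifnot(inherits(series, "esg_series"))
  if (any(g < 0 | g > 0.9)) {
    stop("series expansions are certified for baseline CDF values in ",
         "[0, 0.9] only", call. = FALSE)
  }
  co <- series$coefficients
  vapply(g, function(gv) {
    if (gv == 0) sum(co$coef[co$power == 0]) else sum(co$coef * gv^co$power)
  }, numeric(1))
}

#' @export
print.esg_series <- function(x, ...) {
  cat("<esg_series> kind:", x$kind, " exponent:", x$exponent,
      " terms:", nrow(x$coefficients), "\n")
  invisible(x)
}

#' Series-expansion coefficients of the ESG density
#'
#' The ESG density can be written as a series of exponentiated-baseline
#' densities,
#' \deqn{f(x) = \sum_k D^{(1)}_k\, g\, G^{2k+\alpha-1}
#'   + \sum_{k,i,l} D^{(2)}_{i,k,l}\, g\, G^{2(i+l+k)+\alpha-1},}
#' with \eqn{D^{(1)}_k = \alpha(-1)^k (\pi/2)^{2k+\alpha} / (2k)!} and
#' \eqn{D^{(2)}_{i,k,l} = D^{(1)}_k \binom{\alpha-1}{l} b_i^{(l)}}. Terms are
#' grouped by the total index \eqn{m = i + l + k}, so the returned
#' coefficients pair with powers \eqn{G^{2m+\alpha-1}}.
#'
#' @param alpha Positive power parameter.
#' @param K Truncation order in each series index.
#' @return An `esg_series` whose rows hold the combined coefficient of
#'   \eqn{G^{2m+\alpha-1}} for \eqn{m = 0, \dots, K}.
#' @export
desg_series_coefs <- function(alpha, K = 25) {
  check_positive(alpha, "alpha")
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  k <- 0:K
  D1 <- alpha * (-1)^k * (pi / 2)^(2 * k + alpha) / factorial(2 * k)
  comb <- D1  # m = k contribution from the first sum
  lmax <- if (alpha == round(alpha)) min(K, alpha - 1) else K
  if (lmax >= 1) {
    a <- sine_inner_coefs(K)
    for (l in seq_len(lmax)) {
      b <- power_series_pow(a, l, K)
      wl <- choose(alpha - 1, l)
      for (m in l:K) {
        # i + k = m - l with i, k >= 0
        i <- 0:(m - l)
        comb[m + 1L] <- comb[m + 1L] + sum(wl * D1[m - l - i + 1L] * b[i + 1L])
      }
    }
  }
  structure(list(kind = "pdf-series", exponent = alpha,
                 coefficients = tibble::tibble(power = 2 * (0:K) + alpha - 1,
                                               coef = comb),
                 truncation_order = K, tolerance = 1e-6),
            class = "esg_series")
}

#' Series evaluation of the ESG density
#'
#' Evaluates the density through its exponentiated-baseline series expansion
#' rather than the direct trigonometric form. Intended as a numerical
#' cross-check of the expansion; [desg()] is the production path.
#'
#' @inheritParams desg
#' @param K Truncation order.
#' @return Density values by the truncated series.
#' @seealso [desg_series_coefs()]
#' @export
desg_series <- function(x, alpha, xi = NULL, baseline = baseline_weibull(),
                        K = 25) {
  baseline <- resolve_baseline(baseline)
  xi <- check_esg_params(alpha, xi, baseline)
  sc <- desg_series_coefs(alpha, K)
  g <- baseline$cdf(x, xi)
  eval_series(sc, g) * baseline$pdf(x, xi)
}
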