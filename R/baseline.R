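#' Baseline distribution specifications
#'
#' The ESG family is built by composing a sine transform and a power with an
#' arbitrary continuous baseline CDF \eqn{G(x;\xi)}. A baseline specification
#' bundles the CDF, PDF and quantile function of \eqn{G} together with
#' parameter names, box bounds, and the support of the distribution.
#'
#' @param name Short identifier for the baseline.
#' @param cdf,pdf,quantile Functions of `(x, xi)` (or `(p, xi)` for the
#'   quantile) where `xi` is the numeric baseline parameter vector.
#' @param param_names Character vector of parameter labels, in the order the
#'   functions expect them in `xi`.
#' @param lower,upper Numeric vectors of box bounds per parameter. Defaults:
#'   strictly positive parameters, unbounded above.
#' @param support Length-2 numeric vector giving the support of the
#'   distribution (used as integration limits).
#'
#' @return An object of class `esg_baseline`.
#'
#' @details Built-in baselines are [baseline_weibull()],
#'   [baseline_exponential()] and [baseline_uniform()]. The Weibull baseline
#'   uses the rate-like parameterization \eqn{G(x) = 1 - e^{-\lambda x^\beta}},
#'   i.e. \eqn{\lambda} multiplies \eqn{x^\beta} directly; other Weibull
#'   conventions (scale on \eqn{x}) differ and estimates are not directly
#'   comparable across conventions.
#'
#' @examples
#' wb <- baseline_weibull()
#' wb$cdf(1, c(beta = 2, lambda = 1))
#' @export
esg_baseline <- function(name, cdf, pdf, quantile, param_names,
                         lower = rep(0, length(param_names)),
                         upper = rep(Inf, length(param_names)),
                         support = c(0, Inf)) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(cdf), is.function(pdf), is.function(quantile),
            is.character(param_names),
            length(lower) == length(param_names),
            length(upper) == length(param_names),
            length(support) == 2L)
  structure(
    list(name = name, cdf = cdf, pdf = pdf, quantile = quantile,
         param_names = param_names, lower = lower, upper = upper,
         support = support),
    class = "esg_baseline"
  )
}

#' @export
print.esg_baseline <- function(x, ...) {
  cat("<esg_baseline> ", x$name, " (", paste(x$param_names, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname esg_baseline
#' @export
baseline_weibull <- function() {
  esg_baseline(
    name = "weibull",
    cdf = function(x, xi) ifelse(x <= 0, 0, 1 - exp(-xi[2] * x^xi[1])),
    pdf = function(x, xi) {
      ifelse(x <= 0, 0, xi[1] * xi[2] * x^(xi[1] - 1) * exp(-xi[2] * x^xi[1]))
    },
    quantile = function(p, xi) (-log(1 - p) / xi[2])^(1 / xi[1]),
    param_names = c("beta", "lambda")
  )
}

#' @rdname esg_baseline
#' @export
baseline_exponential <- function() {
  esg_baseline(
    name = "exponential",
    cdf = function(x, xi) ifelse(x <= 0, 0, 1 - exp(-xi[1] * x)),
    pdf = function(x, xi) ifelse(x <= 0, 0, xi[1] * exp(-xi[1] * x)),
    quantile = function(p, xi) -log(1 - p) / xi[1],
    param_names = "rate"
  )
}

#' @rdname esg_baseline
#' @export
baseline_uniform <- function() {
  esg_baseline(
    name = "uniform",
    cdf = function(x, xi) pmin(pmax(x, 0), 1),
    pdf = function(x, xi) as.numeric(x >= 0 & x <= 1),
    quantile = function(p, xi) p,
    param_names = character(0),
    lower = numeric(0), upper = numeric(0),
    support = c(0, 1)
  )
}

# resolve a baseline given either a spec or a built-in name
resolve_baseline <- function(baseline) {
  if (inherits(baseline, "esg_baseline")) return(baseline)
  if (is.character(baseline) && length(baseline) == 1L) {
    return(switch(baseline,
      weibull = baseline_weibull(),
      exponential = baseline_exponential(),
      uniform = baseline_uniform(),
      stop("unknown baseline '", baseline,
           "'; available: weibull, exponential, uniform", call. = FALSE)
    ))
  }
  stop("`baseline` must be an esg_baseline object or a built-in name",
       call. = FALSE)
}

# validate (alpha, xi) against a baseline; errors name the offending parameter
check_esg_params <- function(alpha, xi, baseline) {
  check_positive(alpha, "alpha")
  xi <- as.numeric(xi)
  if (length(xi) != length(baseline$param_names)) {
    stop("baseline '", baseline$name, "' expects ",
         length(baseline$param_names), " parameter(s): ",
         paste(baseline$param_names, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(xi) | xi <= baseline$lower | xi > baseline$upper)
  if (length(bad)) {
    stop("baseline parameter `", baseline$param_names[bad[1]],
         "` is outside its bounds", call. = FALSE)
  }
  invisible(xi)
}
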