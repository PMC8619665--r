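#' Monte-Carlo study of ESW parameter estimators
#'
#' Repeatedly draws ESW samples by inverse-CDF sampling, fits the model by
#' maximum likelihood (or Bayes), and summarises bias, mean squared error,
#' standard deviation, average confidence/credible-interval length (ALCI)
#' and coverage probability (CP) per parameter and sample size. A master
#' seed spawns one sub-seed per replicate, so results are reproducible and
#' each replicate's stream is independent of how the loop is organized.
#'
#' @param alpha,beta,lambda True parameter values.
#' @param n Vector of sample sizes.
#' @param reps Number of Monte-Carlo replicates per sample size.
#' @param level Confidence level for the intervals.
#' @param estimator `"mle"` or `"bayes"`.
#' @param n_iter,priors MCMC settings for the Bayes estimator.
#' @param seed Master integer seed.
#' @return A tibble with one row per (sample size, parameter): columns
#'   `n`, `term`, `bias`, `mse`, `sd`, `alci`, `cp`, `n_fail`.
#' @examples
#' simulate_mle_study(1.5, 0.5, 1.5, n = c(50, 100), reps = 10, seed = 1)
#' @export
simulate_mle_study <- function(alpha, beta, lambda,
                               n = seq(50, 300, by = 10), reps = 1000,
                               level = 0.95, estimator = c("mle", "bayes"),
                               n_iter = 3000, priors = esw_priors(),
                               seed = NULL) {
  check_esw(alpha, beta, lambda)
  estimator <- match.arg(estimator)
  truth <- c(alpha = alpha, beta = beta, lambda = lambda)
  sub_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max,
                                                 length(n) * reps),
                                      nrow = reps))
  purrr::map_dfr(seq_along(n), function(ni) {
    res <- purrr::map(seq_len(reps), function(r) {
      xs <- resw(n[ni], alpha, beta, lambda, seed = sub_seeds[r, ni])
      tryCatch({
        if (estimator == "mle") {
          fit <- esw_fit(xs, level = level)
          tb <- fit$wald
          tibble::tibble(term = tb$term, est = tb$estimate,
                         lo = tb$conf.low, hi = tb$conf.high)
        } else {
          post <- esw_bayes(xs, priors = priors, n_iter = n_iter,
                            seed = sub_seeds[r, ni])
          tb <- tidy(post, level = level)
          tibble::tibble(term = tb$term, est = tb$estimate,
                         lo = tb$hpd.low, hi = tb$hpd.high)
        }
      }, error = function(e) NULL)
    })
    failed <- sum(vapply(res, is.null, logical(1)))
    dplyr::bind_rows(res) |>
      dplyr::mutate(truth = truth[.data$term]) |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(
        bias = mean(.data$est - .data$truth),
        mse = mean((.data$est - .data$truth)^2),
        sd = stats::sd(.data$est),
        alci = mean(.data$hi - .data$lo),
        cp = mean(.data$lo <= .data$truth & .data$truth <= .data$hi),
        .groups = "drop"
      ) |>
      dplyr::mutate(n = n[ni], n_fail = failed, .before = 1)
  })
}

#' Monte-Carlo study of the stress-strength reliability estimator
#'
#' For each (n, m) cell, draws paired ESW samples, computes the joint MLE
#' and plug-in reliability estimate, and (optionally) bootstrap intervals,
#' summarising mean estimate, SD, bias, MSE and - when `bootstrap_B > 0` -
#' average CI length and coverage for the percentile and studentized
#' intervals.
#'
#' @param alpha1,alpha2,beta1,beta2,lambda True parameters of the two
#'   populations (shared `lambda`).
#' @param sizes List of `c(n, m)` pairs.
#' @param reps Monte-Carlo replicates per cell.
#' @param bootstrap_B Bootstrap replicates per Monte-Carlo replicate; 0
#'   skips the interval study (point-estimate performance only).
#' @param level Confidence level.
#' @param seed Master integer seed.
#' @return A tibble with one row per cell: `n`, `m`, `true_r`, `mean_r`,
#'   `sd`, `bias`, `mse`, `n_fail`, and when bootstrapping also
#'   `alci_bp`, `cp_bp`, `alci_bt`, `cp_bt`.
#' @examples
#' simulate_ss_study(0.8, 0.7, 0.5, 0.6, 0.5, sizes = list(c(20, 20)),
#'                   reps = 5, seed = 1)
#' @export
simulate_ss_study <- function(alpha1, alpha2, beta1, beta2, lambda,
                              sizes = list(c(20, 20), c(30, 20), c(40, 40),
                                           c(40, 60), c(60, 60)),
                              reps = 1000, bootstrap_B = 0, level = 0.95,
                              seed = NULL) {
  true_r <- esw_ss_reliability(alpha1, alpha2, beta1, beta2, lambda)
  sub_seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max,
                                                 length(sizes) * reps),
                                      nrow = reps))
  purrr::map_dfr(seq_along(sizes), function(ci) {
    nm <- sizes[[ci]]
    cell <- purrr::map(seq_len(reps), function(r) {
      rs <- sub_seeds[r, ci]
      tryCatch(with_seed(rs, {
        xs <- qesw(runif(nm[1]), alpha1, beta1, lambda)
        ys <- qesw(runif(nm[2]), alpha2, beta2, lambda)
        fit <- esw_ss_fit(xs, ys)
        out <- tibble::tibble(r_hat = fit$r_hat)
        if (bootstrap_B > 0) {
          bt <- esw_ss_bootstrap(xs, ys, B = bootstrap_B, level = level,
                                 seed = sample.int(.Machine$integer.max, 1),
                                 fit = fit)
          out$bp_lo <- bt$bp_ci[["lower"]]; out$bp_hi <- bt$bp_ci[["upper"]]
          out$bt_lo <- bt$bt_ci[["lower"]]; out$bt_hi <- bt$bt_ci[["upper"]]
        }
        out
      }), error = function(e) NULL)
    })
    failed <- sum(vapply(cell, is.null, logical(1)))
    df <- dplyr::bind_rows(cell)
    out <- tibble::tibble(
      n = nm[1], m = nm[2], true_r = true_r,
      mean_r = mean(df$r_hat), sd = stats::sd(df$r_hat),
      bias = mean(df$r_hat) - true_r,
      mse = mean((df$r_hat - true_r)^2),
      n_fail = failed
    )
    if (bootstrap_B > 0) {
      out$alci_bp <- mean(df$bp_hi - df$bp_lo)
      out$cp_bp <- mean(df$bp_lo <= true_r & true_r <= df$bp_hi)
      out$alci_bt <- mean(df$bt_hi - df$bt_lo)
      out$cp_bt <- mean(df$bt_lo <= true_r & true_r <= df$bt_hi)
    }
    out
  })
}
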