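test_that("the ESW log-likelihood equals the per-observation sum", {
  set.seed(1)
  x <- resw(50, 1.5, 0.9, 0.9)
  for (th in list(c(1.5, 0.9, 0.9), c(0.7, 1.3, 0.5), c(2.2, 0.6, 1.1))) {
    expect_equal(esw_loglik(th, x),
                 sum(log(oracle_esw_pdf(x, th[1], th[2], th[3]))),
                 tolerance = 1e-10)
  }
  expect_equal(esw_loglik(c(1, 1, 1), numeric(0)), 0)
  expect_identical(esw_loglik(c(-1, 1, 1), x), -Inf)
  expect_error(esw_loglik(c(1, 1, 1), c(1, -2)), "positive")
})

test_that("the analytic score matches finite differences", {
  set.seed(2)
  x <- resw(80, 1.5, 0.9, 0.9)
  pts <- list(c(1.5, 0.9, 0.9), c(0.8, 1.4, 0.6), c(2.3, 0.5, 1.2))
  for (th in pts) {
    fd <- fd_grad(function(t) esw_loglik(t, x), th, h = 1e-5)
    expect_equal(unname(esw_score(th, x)), fd, tolerance = 1e-5)
  }
})

test_that("the profile estimate of alpha is the unique score root", {
  set.seed(3)
  x <- resw(60, 1.5, 0.9, 0.9)
  ahat <- esw_alpha_profile(0.9, 0.9, x)
  D <- function(a) esw_score(c(a, 0.9, 0.9), x)[1]
  expect_equal(unname(D(ahat)), 0, tolerance = 1e-10)
  expect_gt(D(ahat / 2), 0)
  expect_lt(D(2 * ahat), 0)
  # artificial data with sum log sin = -n gives alpha-hat = 1:
  # each point solves log sin((pi/2) G(x)) = -1 under (beta, lambda) = (1, 1)
  x1 <- rep(-log(1 - 2 / pi * asin(exp(-1))), 5)
  expect_equal(esw_alpha_profile(1, 1, x1), 1, tolerance = 1e-10)
})

test_that("maximum-likelihood fits recover the benchmark estimates", {
  milk <- esg_dataset("milk")
  fit <- esw_fit(milk)
  expect_equal(unname(fit$theta_hat), c(0.3216, 5.5424, 4.7906),
               tolerance = 0.005)
  expect_equal(fit$loglik, 27.732, tolerance = 1e-4)
  # profile-alpha consistency: profiling alpha at (beta-hat, lambda-hat)
  # reproduces the joint maximum within 1e-6 on the log-likelihood scale
  a_prof <- esw_alpha_profile(fit$theta_hat[2], fit$theta_hat[3], milk)
  expect_equal(esw_loglik(c(a_prof, fit$theta_hat[2], fit$theta_hat[3]),
                          milk), fit$loglik, tolerance = 1e-6)
  # score near zero at the optimum
  expect_true(all(abs(esw_score(fit$theta_full, milk)) < 1e-2))
  bladder <- esg_dataset("bladder")
  fitb <- esw_fit(bladder)
  expect_equal(unname(fitb$theta_hat), c(2.7619, 0.6207, 0.2668),
               tolerance = 0.002)
  expect_equal(fitb$loglik, -410.476, tolerance = 1e-3)
})

test_that("submodel fits are valid restrictions", {
  milk <- esg_dataset("milk")
  full <- esw_fit(milk)
  for (m in c("ese", "sw", "weibull")) {
    sub <- esw_fit(milk, model = m)
    expect_lte(sub$loglik, full$loglik + 1e-6)
    expect_true(all(sub$theta_hat > 0))
  }
  # benchmark submodel values on the milk data
  expect_equal(unname(esw_fit(milk, "sw")$theta_hat), c(2.4894, 2.8311),
               tolerance = 0.01)
  expect_equal(esw_fit(milk, "weibull")$loglik, 21.348, tolerance = 1e-3)
})

test_that("observed information is symmetric, positive definite, exact in its
           alpha block, and matches the numeric route", {
  set.seed(4)
  x <- resw(150, 1.5, 0.9, 0.9)
  fit <- esw_fit(x)
  oi <- esw_obs_info(fit$theta_full, x)
  expect_equal(oi$info, t(oi$info))
  expect_true(all(eigen(oi$info, symmetric = TRUE)$values > 0))
  expect_equal(oi$info["alpha", "alpha"],
               length(x) / fit$theta_full[["alpha"]]^2, tolerance = 1e-6)
  oj <- esw_obs_info(fit$theta_full, x, method = "score_jacobian")
  expect_equal(oi$info, oj$info, tolerance = 1e-4)
  # Wald intervals reproducible from the stored pieces
  se <- sqrt(diag(oi$info_inv))
  expect_equal(fit$wald$conf.high - fit$wald$conf.low,
               unname(2 * qnorm(0.975) * se), tolerance = 1e-6)
})

test_that("observed information on the remission-time data matches the
           published matrix", {
  bladder <- esg_dataset("bladder")
  fit <- esw_fit(bladder)
  I <- esw_obs_info(fit$theta_full, bladder)$info
  ref <- matrix(c(16.71197, -72.64589, -220.8935,
                  -72.64589, 2307.67228, 2847.1163,
                  -220.8935, 2847.1163, 4766.8891), 3, 3)
  expect_equal(unname(I), ref, tolerance = 0.005)
})

test_that("profile log-likelihood curves peak at the MLE", {
  milk <- esg_dataset("milk")
  fit <- esw_fit(milk)
  grid <- seq(0.22, 0.45, length.out = 24)
  prof <- esw_profile(milk, "alpha", grid, init = fit$theta_full)
  expect_lt(abs(grid[which.max(prof$loglik)] - fit$theta_hat[["alpha"]]),
            diff(grid[1:2]) + 1e-9)
  expect_true(all(prof$loglik <= fit$loglik + 1e-6))
  # single sign change of the discrete slope: unimodal profile
  expect_equal(sum(diff(sign(diff(prof$loglik))) != 0), 1)
  # profile at the MLE itself reproduces the maximized likelihood
  prof_at <- esw_profile(milk, "alpha", fit$theta_hat[["alpha"]],
                         init = fit$theta_full)
  expect_equal(prof_at$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("estimates recover the truth at the nominal coverage", {
  truth <- c(1.5, 0.5, 1.5)
  reps <- 500
  set.seed(6)
  seeds <- sample.int(2^31 - 1, reps)
  cover <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    xs <- resw(300, truth[1], truth[2], truth[3], seed = seeds[r])
    fit <- tryCatch(esw_fit(xs), error = function(e) NULL)
    if (is.null(fit)) next
    cover[r, ] <- fit$wald$conf.low <= truth & truth <= fit$wald$conf.high
  }
  cp <- colMeans(cover, na.rm = TRUE)
  expect_true(all(cp > 0.90 & cp < 0.99))
})

test_that("goodness-of-fit statistics match hand values and benchmarks", {
  # single observation with fitted CDF one half
  g1 <- gof_report(1, function(x) rep(0.5, length(x)), 0, 1)
  expect_equal(g1$ks, 0.5)
  milk <- esg_dataset("milk")
  fit <- esw_fit(milk)
  g <- gof_report(milk, fitted_cdf(fit), fit$loglik, 3)
  expect_equal(g$ks, 0.0734, tolerance = 1e-3)
  expect_equal(g$ad, 0.5305, tolerance = 0.05)
  expect_equal(g$cvm, 0.0836, tolerance = 0.05)
  # criteria from the published log-likelihood
  gm <- gof_report(milk, fitted_cdf(fit), 27.732, 3)
  expect_equal(gm$aic, -49.464, tolerance = 1e-3)
  expect_equal(gm$bic, -41.446, tolerance = 1e-3)
  expect_equal(gm$caic, -49.231, tolerance = 1e-3)
})

test_that("the TTT transform matches hand computation and ends at one", {
  t3 <- ttt_points(c(1, 2, 3))
  expect_equal(t3$ttt, c(0.5, 5 / 6, 1))
  set.seed(8)
  x <- resw(40, 1.2, 1.5, 1)
  tx <- ttt_points(x)
  expect_equal(tx$ttt[length(x)], 1)
  expect_true(all(tx$ttt > 0 & tx$ttt <= 1))
  # increasing-hazard data lean concave: most second differences <= 0
  milk <- esg_dataset("milk")
  tm <- ttt_points(milk)
  expect_gt(mean(diff(diff(tm$ttt)) <= 0), 0.5)
})
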