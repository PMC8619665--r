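test_that("baseline specifications satisfy their contract", {
  for (b in list(baseline_weibull(), baseline_exponential(),
                 baseline_uniform())) {
    xi <- switch(b$name, weibull = c(1.3, 0.8), exponential = 1.7,
                 uniform = numeric(0))
    p <- seq(0.01, 0.99, by = 0.07)
    q <- b$quantile(p, xi)
    expect_equal(b$cdf(q, xi), p, tolerance = 1e-9)
    expect_true(all(diff(b$cdf(seq(0.01, 3, length.out = 50), xi)) >= 0))
    expect_true(all(b$pdf(seq(0.01, 3, length.out = 50), xi) >= 0))
  }
  expect_error(pesg(1, 1, NULL, "nope"), "unknown")
})

test_that("ESG CDF matches closed forms and is a valid CDF", {
  # alpha = 1 at G = 0.5, and alpha = 2 halving
  x_half <- qweibull(0.5, 1, 1)  # G(x) = 0.5 for unit exponential baseline
  expect_equal(pesg(x_half, 1, c(1, 1)), sin(pi / 4), tolerance = 1e-12)
  expect_equal(pesg(x_half, 2, c(1, 1)), 0.5, tolerance = 1e-12)
  expect_equal(pesg(log(2), 0.5, c(1, 1)), sqrt(sin(pi / 4)),
               tolerance = 1e-4)
  grid <- seq(0.01, 6, length.out = 200)
  for (alpha in c(0.4, 1, 2.7)) {
    v <- pesg(grid, alpha, c(1.5, 0.5))
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
  # power ordering: alpha >= 1 lowers the CDF, alpha < 1 raises it
  base <- pesg(grid, 1, c(1.5, 0.5))
  expect_true(all(pesg(grid, 2, c(1.5, 0.5)) <= base + 1e-15))
  expect_true(all(pesg(grid, 0.5, c(1.5, 0.5)) >= base - 1e-15))
  expect_error(pesg(1, -1, c(1, 1)), "alpha")
  expect_error(pesg(1, 1, c(1, -2)), "lambda")
})

test_that("ESG density integrates to one and differentiates the CDF", {
  expect_equal(desg(0.5, 1, NULL, baseline_uniform()),
               pi / 2 * cos(pi / 4), tolerance = 1e-12)
  # finite-difference oracle at 20 interior points
  xs <- seq(0.2, 2.5, length.out = 20)
  fd <- vapply(xs, function(x) {
    fd_deriv(function(z) pesg(z, 1.5, c(0.5, 1.5)), x)
  }, numeric(1))
  expect_equal(desg(xs, 1.5, c(0.5, 1.5)), fd, tolerance = 1e-6)
  # normalization panel
  for (par in list(c(1.5, 0.5, 1.5), c(0.7, 1.2, 0.8), c(2.5, 2, 1))) {
    z <- integrate(function(x) desg(x, par[1], par[2:3]), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  # divergence sentinel at the lower endpoint for alpha < 1
  expect_identical(desg(0, 0.5, c(2, 1)), Inf)
})

test_that("survival and hazard satisfy their identities and tail law", {
  xs <- seq(0.1, 3, length.out = 20)
  sh <- esg_sf_hrf(xs, 1.5, c(0.5, 1.5))
  expect_equal(sh$sf + pesg(xs, 1.5, c(0.5, 1.5)), rep(1, 20))
  expect_equal(sh$hrf * sh$sf, desg(xs, 1.5, c(0.5, 1.5)),
               tolerance = 1e-10)
  # tail equivalence s(x) ~ (alpha pi^2 / 8) (1 - G)^2 as G -> 1
  for (alpha in c(0.8, 1.7)) {
    gv <- 1 - 1e-4
    x <- qweibull(gv, 1.2, 1)
    s <- 1 - pesg(x, alpha, c(1.2, 1))
    expect_equal(s / (alpha * pi^2 / 8 * (1 - gv)^2), 1, tolerance = 1e-3)
  }
})

test_that("quantiles invert the CDF and the median solves F = 1/2", {
  expect_equal(qesg(0.5, 1, c(1, 1)),
               -log(1 - 2 / pi * asin(0.5)), tolerance = 1e-12)
  expect_equal(qesg(0.5, 1, c(1, 1)), log(3 / 2), tolerance = 1e-12)
  xs <- seq(0.1, 3, by = 0.1)
  expect_equal(qesg(pesg(xs, 1.5, c(0.5, 1.5)), 1.5, c(0.5, 1.5)), xs,
               tolerance = 1e-8)
  med <- esg_median(1.5, c(0.5, 1.5))
  med_oracle <- bisect(function(x) pesg(x, 1.5, c(0.5, 1.5)) - 0.5,
                       1e-8, 50)
  expect_equal(med, med_oracle, tolerance = 1e-9)
  expect_error(qesg(1.2, 1, c(1, 1)), "inside")
})

test_that("inverse-CDF sampling is reproducible and distributionally right", {
  s1 <- resg(500, 1.5, c(0.9, 0.9), seed = 7)
  s2 <- resg(500, 1.5, c(0.9, 0.9), seed = 7)
  expect_identical(s1, s2)
  n <- 50000
  draws <- resg(n, 1.5, c(0.9, 0.9), seed = 11)
  u <- sort(pesg(draws, 1.5, c(0.9, 0.9)))
  ks <- max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
  expect_lt(ks, 0.01)
  # sample mean vs quadrature mean within 3 standard errors
  mu <- esg_moment(1, 1.5, c(0.9, 0.9))
  mu2 <- esg_moment(2, 1.5, c(0.9, 0.9))
  se <- sqrt((mu2 - mu^2) / n)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("moments are normalized and satisfy Jensen's inequality", {
  expect_equal(esg_moment(0, 1.5, c(0.5, 1.5)), 1, tolerance = 1e-9)
  for (par in list(c(1.5, 0.5, 1.5), c(0.8, 1.3, 0.7), c(2, 2, 1))) {
    m1 <- esg_moment(1, par[1], par[2:3])
    m2 <- esg_moment(2, par[1], par[2:3])
    expect_gt(m2, m1^2)
  }
})

test_that("Renyi entropy matches its closed form and series integrand", {
  # alpha = 1 on the uniform baseline: integral of (pi/2)^2 cos^2 is pi^2/8
  expect_equal(esg_renyi(2, 1, NULL, baseline_uniform()),
               -log(pi^2 / 8), tolerance = 1e-8)
  # series-route integrand vs direct integrand at an interior point
  f_ser <- esg_renyi(2.5, 1.7, c(1, 1), series_integrand = TRUE)
  x <- qweibull(0.4, 1, 1)
  expect_equal(f_ser(x), desg(x, 1.7, c(1, 1))^2.5, tolerance = 1e-6)
  # scaling x -> c x shifts entropy by log(c) (change of variables)
  h1 <- esg_renyi(2, 1.5, c(1, 1))
  h2 <- esg_renyi(2, 1.5, c(1, 0.5))  # rate halved = scale doubled
  expect_equal(h2 - h1, log(2), tolerance = 1e-6)
})

test_that("closed-form stress-strength reliability behaves", {
  expect_equal(ss_reliability_closed(0.7, 0.7), 0.5)
  expect_equal(ss_reliability_closed(0.8, 0.7), 8 / 15)
  a <- c(0.3, 0.9, 1.7, 4)
  for (i in seq_along(a)) {
    expect_equal(ss_reliability_closed(a[i], 2) +
                   ss_reliability_closed(2, a[i]), 1)
  }
  r_seq <- vapply(a, ss_reliability_closed, numeric(1), alpha2 = 1.1)
  expect_true(all(diff(r_seq) > 0))
  # Monte-Carlo oracle with a shared baseline
  n <- 200000
  x <- resg(n, 1.4, c(1.2, 0.8), seed = 3)
  y <- resg(n, 0.6, c(1.2, 0.8), seed = 4)
  r_mc <- mean(y < x)
  r <- ss_reliability_closed(1.4, 0.6)
  expect_lt(abs(r_mc - r), 3 * sqrt(r * (1 - r) / n))
})
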