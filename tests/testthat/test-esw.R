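test_that("ESW closed forms agree with the generic family code", {
  expect_equal(pesw(log(2), 1, 1, 1), sin(pi / 4), tolerance = 1e-12)
  expect_equal(pesw(log(2), 2, 1, 1), 0.5, tolerance = 1e-12)
  xs <- seq(0.05, 4, length.out = 30)
  for (par in list(c(1.5, 0.5, 1.5), c(0.8, 2, 0.7))) {
    expect_equal(pesw(xs, par[1], par[2], par[3]),
                 pesg(xs, par[1], par[2:3]), tolerance = 1e-12)
    expect_equal(desw(xs, par[1], par[2], par[3]),
                 desg(xs, par[1], par[2:3]), tolerance = 1e-12)
    f <- esw_functions(xs, par[1], par[2], par[3])
    expect_equal(f$hrf * f$sf, f$pdf, tolerance = 1e-12)
    expect_equal(f$cdf + f$sf, rep(1, 30))
  }
  expect_equal(pesw(-1, 1.5, 1, 1), 0)
  expect_equal(desw(c(-1, 0), 2, 1, 1), c(0, 0))
})

test_that("ESW small- and large-x asymptotic equivalences hold", {
  a <- 1.4; b <- 0.8; l <- 1.2
  x0 <- 1e-4
  expect_equal(pesw(x0, a, b, l) / ((pi / 2)^a * l^a * x0^(a * b)), 1,
               tolerance = 1e-2)
  xb <- qesw(1 - 1e-7, a, b, l)
  expect_equal(sesw(xb, a, b, l) / (a * pi^2 / 8 * exp(-2 * l * xb^b)), 1,
               tolerance = 1e-2)
})

test_that("ESW quantiles are exact inverses with power-law scale", {
  expect_equal(qesw(0.5, 1, 1, 1), log(3 / 2), tolerance = 1e-12)
  xs <- seq(0.05, 5, by = 0.15)
  expect_equal(qesw(pesw(xs, 1.5, 0.5, 1.5), 1.5, 0.5, 1.5), xs,
               tolerance = 1e-9)
  q <- qesw(c(0.25, 0.5, 0.75), 1.5, 0.5, 1.5)
  expect_true(all(diff(q) > 0))
  # lambda scaling: Q(p; c lambda) = c^{-1/beta} Q(p; lambda)
  p <- c(0.1, 0.5, 0.9)
  expect_equal(qesw(p, 1.3, 0.7, 3 * 1.1),
               3^(-1 / 0.7) * qesw(p, 1.3, 0.7, 1.1), tolerance = 1e-12)
  expect_error(qesw(0, 1, 1, 1), "inside")
})

test_that("Bowley and Moors shape measures are scale-free and bounded", {
  for (ab in list(c(0.5, 0.5), c(1.5, 2), c(3, 3))) {
    bm1 <- esw_bowley_moors(ab[1], ab[2], 0.5)
    bm2 <- esw_bowley_moors(ab[1], ab[2], 5)
    expect_equal(bm1$bowley, bm2$bowley, tolerance = 1e-12)
    expect_equal(bm1$moors, bm2$moors, tolerance = 1e-12)
    expect_true(abs(bm1$bowley) < 1)
  }
  expect_gt(esw_bowley_moors(0.5, 0.5)$bowley,
            esw_bowley_moors(3, 3)$bowley)
})

test_that("moments by quadrature match independent routes", {
  # mean equals the integral of the survival function
  mu <- esw_moment(1, 1, 1, 1)
  mu_sf <- integrate(function(x) sesw(x, 1, 1, 1), 0, Inf,
                     rel.tol = 1e-10)$value
  expect_equal(mu, mu_sf, tolerance = 1e-7)
  # Monte-Carlo oracle
  n <- 1e6
  draws <- resw(n, 1.6, 0.6, 1.4, seed = 5)
  m1 <- esw_moment(1, 1.6, 0.6, 1.4)
  m2 <- esw_moment(2, 1.6, 0.6, 1.4)
  expect_lt(abs(mean(draws) - m1), 3 * sqrt((m2 - m1^2) / n))
  # variance positivity
  for (par in list(c(1.5, 0.5, 1.5), c(0.8, 1.3, 0.7), c(2.5, 2, 1))) {
    expect_gt(esw_moment(2, par[1], par[2], par[3]),
              esw_moment(1, par[1], par[2], par[3])^2)
  }
})

test_that("the gamma-series integral psi matches quadrature", {
  quad_psi <- function(w1, w2, w3, b, l) {
    integrate(function(x) {
      g <- b * l * x^(b - 1) * exp(-l * x^b)
      x^w1 * g^w2 * (1 - exp(-l * x^b))^w3
    }, 0, Inf, rel.tol = 1e-11)$value
  }
  expect_equal(esw_psi(1, 1, 0.5, 1, 1), quad_psi(1, 1, 0.5, 1, 1),
               tolerance = 1e-7)
  expect_equal(esw_psi(2, 1, 1.5, 2, 0.7), quad_psi(2, 1, 1.5, 2, 0.7),
               tolerance = 1e-7)
  expect_error(esw_psi(-3, 1, 0.5, 1, 1), "positive")
})

test_that("series and quadrature moment routes agree", {
  for (par in list(c(1.6, 0.6, 1.4), c(1.3, 1.1, 0.9), c(2.4, 0.8, 1.2))) {
    for (r in 1:2) {
      expect_equal(esw_moment(r, par[1], par[2], par[3], "series"),
                   esw_moment(r, par[1], par[2], par[3], "quadrature"),
                   tolerance = 1e-5)
    }
  }
  expect_error(esw_moment(1, 2, 0.8, 1, "series"), "noninteger")
})

test_that("mean residual life: exact value, asymptote, monotonicity", {
  # at t = 0 the MRL is the mean
  mr0 <- esw_mean_residual_life(1e-12, 1.5, 0.9, 0.9)
  expect_equal(mr0$exact, esw_moment(1, 1.5, 0.9, 0.9), tolerance = 1e-6)
  # deep-tail ratio to the incomplete-gamma asymptote
  tt <- qesw(1 - 1e-6, 1.5, 0.9, 0.9)
  mrt <- esw_mean_residual_life(tt, 1.5, 0.9, 0.9)
  expect_gt(mrt$exact / mrt$asymptotic, 0.95)
  expect_lt(mrt$exact / mrt$asymptotic, 1.05)
  # decreasing in t for an increasing-hazard parameter set
  ts <- c(0.2, 0.6, 1.0, 1.5)
  vals <- vapply(ts, function(t) {
    esw_mean_residual_life(t, 1.5, 2, 1)$exact
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(esw_mean_residual_life(50, 1.5, 2, 1), "underflow")
})

test_that("reversed mean residual life: limit, bound, Monte-Carlo", {
  r <- esw_reversed_mrl(1e-3, 1.5, 0.5, 1.5)
  expect_equal(r$exact / r$asymptotic, 1, tolerance = 0.05)
  for (t in c(0.5, 1, 2)) {
    expect_lt(esw_reversed_mrl(t, 1, 1, 1)$exact, t)
  }
  # Monte-Carlo E(t - X | X <= t) at t = 2
  n <- 1e6
  draws <- resw(n, 1, 1, 1, seed = 9)
  below <- draws[draws <= 2]
  mc <- mean(2 - below)
  ex <- esw_reversed_mrl(2, 1, 1, 1)$exact
  expect_lt(abs(mc - ex), 3 * sd(2 - below) / sqrt(length(below)))
})

test_that("order-statistic densities: forms agree and normalize", {
  xs <- seq(0.1, 3, length.out = 10)
  expect_equal(esw_order_stat_pdf(xs, 1, 1, 1.5, 0.9, 0.9),
               desw(xs, 1.5, 0.9, 0.9))
  # maximum of three: 3 f F^2
  expect_equal(esw_order_stat_pdf(xs, 3, 3, 1.2, 1.1, 0.8),
               3 * desw(xs, 1.2, 1.1, 0.8) * pesw(xs, 1.2, 1.1, 0.8)^2,
               tolerance = 1e-12)
  # mixture identity
  expect_equal(esw_order_stat_pdf(xs, 2, 5, 1.5, 0.9, 0.9, "mixture"),
               esw_order_stat_pdf(xs, 2, 5, 1.5, 0.9, 0.9, "direct"),
               tolerance = 1e-10)
  z <- integrate(function(x) esw_order_stat_pdf(x, 2, 5, 1.5, 0.9, 0.9),
                 0, Inf, rel.tol = 1e-9)$value
  expect_equal(z, 1, tolerance = 1e-7)
  expect_error(esw_order_stat_pdf(1, 6, 5, 1, 1, 1), "index")
})

test_that("normalized sample minima approach the Weibull limit law", {
  lim <- esw_extreme_min_limit(1, 0.5, 2)  # alpha beta = 1
  expect_equal(lim$cdf, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(esw_extreme_min_limit(1e-12, 1.5, 0.5)$cdf, 0,
               tolerance = 1e-6)
  # simulation: 5000 minima of samples of size 2000
  nrep <- 5000; nn <- 2000
  bn <- qesw(1 / nn, 1.5, 0.5, 1.5)
  mins <- with(list(), {
    set.seed(21)
    u <- matrix(runif(nrep), nrep, 1)
    # min of n draws has CDF 1 - (1 - F)^n; invert directly
    qesw(1 - (1 - u)^(1 / nn), 1.5, 0.5, 1.5) / bn
  })
  grid <- sort(mins)
  lim_cdf <- 1 - exp(-grid^(1.5 * 0.5))
  ks <- max(abs(seq_len(nrep) / nrep - lim_cdf))
  expect_lt(ks, 0.05)
})

test_that("density monotonicity matches the shape theorem", {
  grid <- seq(0.01, 5, length.out = 200)
  expect_true(esw_pdf_nonincreasing(0.8, 0.9, 0.5, grid))
  expect_true(esw_pdf_nonincreasing(1, 1, 2, grid))
  expect_false(esw_pdf_nonincreasing(1.5, 2, 1, grid))
})
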