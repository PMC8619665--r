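# independent oracles used across the test files; each is deliberately
# naive (brute force / direct numerics) and shares no code with the package

# polynomial product by explicit convolution
poly_mult <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
  }
  out
}

poly_pow <- function(a, n) {
  out <- 1
  for (k in seq_len(n)) out <- poly_mult(out, a)
  out
}

# bisection root of f on [lo, hi]
bisect <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# central finite-difference derivative
fd_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- replace(numeric(length(x)), j, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# exhaustive-search HPD: try every window of m consecutive order statistics
hpd_brute <- function(draws, level) {
  s <- sort(draws)
  T <- length(s)
  m <- ceiling(level * T)
  best <- c(s[1], s[T])
  if (m >= T) return(best)
  for (i in 1:(T - m)) {
    if (s[i + m] - s[i] < best[2] - best[1] - 1e-15) {
      best <- c(s[i], s[i + m])
    }
  }
  best
}

# ESW density/CDF re-expressed from first principles (no package code)
oracle_esw_pdf <- function(x, a, b, l) {
  G <- 1 - exp(-l * x^b)
  g <- b * l * x^(b - 1) * exp(-l * x^b)
  a * pi / 2 * g * cos(pi / 2 * G) * sin(pi / 2 * G)^(a - 1)
}

oracle_esw_cdf <- function(x, a, b, l) {
  sin(pi / 2 * (1 - exp(-l * x^b)))^a
}
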