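# Calibration of sampling distributions from (min, central, max) ranges.

test_that("truncated normal calibration reads the range as +/-2 sd", {
  d <- dist_truncnorm(quantity_range(13.8, 14.5, 15.2))
  expect_equal(d$family, "truncated_normal")
  expect_equal(d$mean, 14.5)
  expect_equal(d$sd, 0.35)
  expect_equal(c(d$lower, d$upper), c(13.8, 15.2))

  # central estimate need not be the midpoint
  d2 <- dist_truncnorm(quantity_range(0.7, 1.9, 3.0, "%/yr"))
  expect_equal(d2$mean, 1.9)
  expect_equal(d2$sd, 0.575)

  # degenerate range collapses to a point mass
  expect_equal(dist_truncnorm(quantity_range(5, 5, 5))$family, "point_mass")

  # zero-truncation variant keeps the calibrated moments, drops the range
  dz <- dist_truncnorm(quantity_range(0.7, 1.9, 3.0, "%/yr"), truncation = "zero")
  expect_equal(c(dz$lower, dz$upper), c(0, Inf))
})

test_that("shifted gamma starts at the reported minimum", {
  marsh <- dist_shifted_gamma(quantity_range(2.2, 5.1, 40), 1.6, 6)
  expect_equal(marsh$location, 2.2)
  expect_equal(c(marsh$shape, marsh$scale), c(1.6, 6))
  expect_equal(marsh$upper, Inf)

  unshifted <- dist_shifted_gamma(quantity_range(17.7, 30, 60), 4, 4, shift = FALSE)
  expect_equal(unshifted$location, 0)

  expect_error(dist_shifted_gamma(quantity_range(1, 2, 3), -1, 6), "positive")
  expect_error(dist_shifted_gamma(quantity_range(1, 2, 3), 2, 0), "positive")
})

test_that("exact quantiles match closed forms", {
  expect_equal(dist_quantile(dist_point(5), 0.5), 5)
  # shifted gamma with shape 1 is exponential: median ln 2
  expo <- dist_shifted_gamma(quantity_range(1, 2, 3), 1, 1, shift = FALSE)
  expect_equal(dist_quantile(expo, 0.5), log(2), tolerance = 1e-10)
  expect_equal(round(dist_quantile(expo, 0.5), 4), 0.6931)
  # symmetric truncated normal: median at the central estimate
  sym <- dist_truncnorm(quantity_range(10, 15, 20))
  expect_equal(dist_quantile(sym, 0.5), 15)
  expect_error(dist_quantile(sym, 0), "strictly in")
  expect_error(dist_quantile(sym, 1), "strictly in")
})

test_that("truncated-normal quantiles agree with a rejection-sampling oracle", {
  # independent route: raw normal draws filtered to the range
  set.seed(31)
  d <- dist_truncnorm(quantity_range(0.7, 1.9, 3.0, "%/yr"))
  raw <- rnorm(4e5, 1.9, 0.575)
  kept <- raw[raw >= 0.7 & raw <= 3.0]
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(dist_quantile(d, p), quantile(kept, p, names = FALSE),
      tolerance = 0.01
    )
  }
})

test_that("sampling is inverse-CDF: support containment and convergence", {
  set.seed(21)
  d <- dist_truncnorm(quantity_range(13.8, 14.5, 15.2))
  x <- dist_sample(d, 50000)
  expect_true(all(x >= 13.8 & x <= 15.2))
  # truncation at +/-2 sd barely moves the mean; standard-error bound
  expect_lt(abs(mean(x) - 14.5), 3 * 0.35 / sqrt(50000) + 0.01)

  g <- dist_shifted_gamma(quantity_range(2.2, 5.1, 40), 1.6, 6)
  y <- dist_sample(g, 50000)
  expect_gte(min(y), 2.2)

  expect_equal(dist_sample(dist_point(5), 10), rep(5, 10))
  expect_error(dist_sample(d, 0), "count")
})

test_that("empirical quantiles converge to exact ones at MC rate", {
  set.seed(22)
  specs <- list(
    dist_truncnorm(quantity_range(0.4, 1.5, 2.6, "%/yr")),
    dist_shifted_gamma(quantity_range(17.7, 30, 60), 4, 4),
    dist_lognormal(0.2, 0.3)
  )
  # exact density of each family, for the asymptotic quantile se
  dens_at <- function(d, q) {
    switch(d$family,
      truncated_normal = dnorm(q, d$mean, d$sd) /
        (pnorm(d$upper, d$mean, d$sd) - pnorm(d$lower, d$mean, d$sd)),
      shifted_gamma = dgamma(q - d$location, shape = d$shape, scale = d$scale),
      lognormal = dlnorm(q, d$meanlog, d$sdlog)
    )
  }
  n <- 50000
  for (d in specs) {
    x <- dist_sample(d, n)
    for (p in c(0.05, 0.5, 0.95)) {
      q <- dist_quantile(d, p)
      # asymptotic se of an empirical quantile: sqrt(p(1-p)/n)/f(q)
      se <- sqrt(p * (1 - p) / n) / dens_at(d, q)
      expect_lt(abs(quantile(x, p, names = FALSE) - q), 3 * se)
    }
  }
})

test_that("draws never escape the truncation range over many seeds", {
  d <- dist_truncnorm(quantity_range(0.7, 1.9, 3.0, "%/yr"))
  for (s in 1:25) {
    set.seed(s)
    x <- dist_sample(d, 2000)
    expect_true(all(x >= 0.7 & x <= 3.0))
  }
})

test_that("normal-family draws are affine equivariant in the range", {
  k <- 3.7
  r <- quantity_range(10, 12, 18)
  rk <- quantity_range(10 * k, 12 * k, 18 * k)
  set.seed(77)
  a <- dist_sample(dist_truncnorm(r), 1000)
  set.seed(77)
  b <- dist_sample(dist_truncnorm(rk), 1000)
  expect_equal(b, k * a, tolerance = 1e-12)
})
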