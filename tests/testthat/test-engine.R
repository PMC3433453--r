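# The Monte Carlo propagation pipeline.

test_that("inputs table validation names the offending ecosystem", {
  expect_error(
    bc_ecosystem("bad", extent = c(5, 4, 6), rate = c(1, 1.5, 2),
      sediment_c = 100, biomass_c = 10
    ),
    "minimum <= central <= maximum"
  )
  expect_error(
    bc_ecosystem("marsh", extent = c(2.2, 5.1, 40), rate = c(1, 1.5, 2),
      sediment_c = 100, biomass_c = 10, extent_family = "gamma"
    ),
    "gamma_shape"
  )
  two <- dplyr::bind_rows(mangrove_row(), mangrove_row())
  expect_error(bc_simulate(two, n_iterations = 10), "unique")
})

test_that("summaries use linear interpolation on order statistics", {
  expect_equal(bc_summarize(1:100)[["lower"]], 5.95)
  expect_equal(bc_summarize(rep(3, 10)), c(lower = 3, median = 3, upper = 3))
  expect_error(bc_summarize(numeric(0)), "nonempty")
  expect_error(bc_summarize(1:10, c(0.5, 0.05, 0.95)), "increasing")

  # against the hand-written interpolation oracle on irregular data
  set.seed(41)
  x <- rlnorm(501, 0, 1.3)
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(
      bc_summarize(x, c(0.01, p, 0.99))[["median"]],
      quantile_by_hand(x, p)
    )
  }

  # 50,000 standard-normal draws: p5 near the analytic -1.645
  set.seed(42)
  z <- rnorm(50000)
  expect_equal(bc_summarize(z)[["lower"]], qnorm(0.05), tolerance = 0.03)
})

test_that("factor draws respect each family's support", {
  sim <- bc_simulate(bc_table1(), n_iterations = 5000, seed = 8)
  d <- sim$draws
  mang <- d[d$ecosystem == "mangrove", ]
  expect_true(all(mang$extent >= 13.8 & mang$extent <= 15.2))
  expect_true(all(mang$rate >= 0.7 & mang$rate <= 3.0))
  expect_true(all(mang$density >= 373 & mang$density <= 1492))
  marsh <- d[d$ecosystem == "tidal_marsh", ]
  expect_gte(min(marsh$extent), 2.2)
  expect_gt(max(marsh$extent), 40) # unbounded above: tail exceeds the printed max
  # emissions column is exactly the unit-converted elementwise product
  expect_equal(d$emissions, emissions_point(d$extent, d$rate, d$density))
})

test_that("degenerate configuration reduces to the closed-form product", {
  sim <- bc_simulate(degenerate_row(), n_iterations = 500, seed = 1)
  expect_equal(
    unlist(sim$summary[1, c("lower", "median", "upper")]),
    rep(emissions_point(10, 2, 500), 3),
    ignore_attr = TRUE
  )
  expect_equal(sim$total$upper - sim$total$lower, 0)
})

test_that("same seed gives bit-identical results, regardless of row order", {
  inputs <- bc_table1()
  a <- bc_simulate(inputs, n_iterations = 2000, seed = 99)
  b <- bc_simulate(inputs, n_iterations = 2000, seed = 99)
  expect_identical(tidy(a), tidy(b))
  # reversing ecosystem order must not change any per-ecosystem number
  c <- bc_simulate(inputs[3:1, ], n_iterations = 2000, seed = 99)
  expect_identical(
    dplyr::arrange(a$summary, ecosystem),
    dplyr::arrange(c$summary, ecosystem)
  )
  d <- bc_simulate(inputs, n_iterations = 2000, seed = 100)
  expect_false(identical(tidy(a), tidy(d)))
})

test_that("column_sum totals add per-ecosystem statistics; distribution_sum is never wider", {
  sim <- bc_simulate(bc_table1(), n_iterations = 5000, seed = 13)
  expect_equal(sim$total$lower, sum(sim$summary$lower))
  expect_equal(sim$total$median, sum(sim$summary$median))
  expect_equal(sim$total$upper, sum(sim$summary$upper))

  dsum <- bc_total(sim, "distribution_sum")
  expect_lte(dsum$upper, sim$total$upper)
  expect_gte(dsum$lower, sim$total$lower)
  # conservation: total draws are exactly the per-iteration sums
  td <- bc_total_draws(sim)
  by_hand <- rowSums(matrix(sim$draws$emissions, ncol = 3))
  expect_equal(sort(td), sort(by_hand))

  # point masses agree under both conventions
  flat <- dplyr::bind_rows(
    degenerate_row("a", 10, 1, 100),
    degenerate_row("b", 20, 1, 100),
    degenerate_row("c", 30, 1, 100)
  )
  fsim <- bc_simulate(flat, n_iterations = 100, seed = 1)
  expect_equal(bc_total(fsim, "column_sum"), bc_total(fsim, "distribution_sum"))
})

test_that("scaling one ecosystem's density range scales its statistics", {
  inputs <- bc_table1()
  k <- 2.5
  scaled <- inputs
  scaled$total_co2[scaled$ecosystem == "mangrove"] <- 1492 * k
  a <- bc_simulate(inputs, n_iterations = 2000, seed = 5)
  b <- bc_simulate(scaled, n_iterations = 2000, seed = 5)
  expect_equal(
    unlist(b$summary[b$summary$ecosystem == "mangrove", -1]),
    k * unlist(a$summary[a$summary$ecosystem == "mangrove", -1]),
    tolerance = 1e-12
  )
  # other ecosystems untouched (private substreams)
  expect_equal(
    a$summary[a$summary$ecosystem == "seagrass", ],
    b$summary[b$summary$ecosystem == "seagrass", ]
  )
})

test_that("engine quantiles match the product-lognormal closed form", {
  oc <- synth_oracle(seed = 7)
  n <- 50000
  sim <- bc_simulate_dists(oc$dist_tbl, n_iterations = n, seed = 17)
  sigma <- sqrt(sum(oc$sdlog^2))
  for (j in 1:3) {
    p <- c(0.05, 0.5, 0.95)[j]
    q <- oc$quantiles[[j]]
    # lognormal density at the quantile gives the asymptotic MC se
    dens <- dlnorm(q / 1e-5, sum(oc$meanlog), sigma) / 1e-5
    se <- sqrt(p * (1 - p) / n) / dens
    expect_lt(abs(unlist(sim$summary[1, 1 + j]) - q), 3 * se)
  }
})

test_that("tidiers expose the summary and run settings", {
  sim <- bc_simulate(bc_table1(), n_iterations = 1000, seed = 2)
  td <- tidy(sim)
  expect_equal(nrow(td), 4)
  expect_equal(td$ecosystem, c("tidal_marsh", "mangrove", "seagrass", "Total"))
  expect_true(all(td$lower <= td$median & td$median <= td$upper))
  gl <- glance(sim)
  expect_equal(gl$n_iterations, 1000)
  expect_equal(gl$seed, 2)
  expect_equal(gl$total_median, sim$total$median)
})
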