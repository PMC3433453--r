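# Shared fixtures, all built in code.

# The published mangrove row (all-normal inputs, the most robust one).
mangrove_row <- function() {
  bc_ecosystem("mangrove",
    extent = c(13.8, 14.5, 15.2), rate = c(0.7, 1.9, 3.0),
    sediment_c = 280, biomass_c = 127, total_co2 = 1492
  )
}

# A fully degenerate ecosystem: every factor a point mass, so the pipeline
# has a closed-form answer.
degenerate_row <- function(name = "flat", extent = 10, rate = 2, co2 = 500) {
  bc_ecosystem(name,
    extent = rep(extent, 3), rate = rep(rate, 3),
    sediment_c = co2 * 12 / 44, biomass_c = 0, total_co2 = co2,
    loss = c(1, 1, 1)
  )
}

# Empirical quantile by the linear-interpolation definition on order
# statistics, written out by hand as an independent check on bc_summarize.
quantile_by_hand <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
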