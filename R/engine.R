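# Monte Carlo propagation engine.
#
# Per ecosystem, three independent factors (extent, conversion rate,
# susceptible carbon density) are sampled from distributions calibrated to
# their published ranges; per-iteration emissions are the unit-converted
# product; 90% intervals are the empirical 5th/95th percentiles of the
# 50,000 draws.

#' Assemble one ecosystem's input row
#'
#' Builds a single validated row of the inputs table from published ranges:
#' global extent (Mha), annual conversion rate (%/yr), near-surface carbon
#' stocks (Mg C/ha), and the loss-fraction bounds applied to the stock. The
#' total CO2-equivalent stock is `(sediment_c + biomass_c) * 44/12` unless
#' `total_co2` is supplied directly (as when reproducing a published table
#' whose printed per-hectare CO2 values carry their own rounding).
#'
#' @param ecosystem Ecosystem name (used to derive its RNG substream).
#' @param extent A length-3 numeric `c(min, central, max)` in Mha.
#' @param rate A length-3 numeric `c(min, central, max)` in %/yr.
#' @param sediment_c,biomass_c Carbon stocks in Mg C/ha (top meter of
#'   sediment; emergent biomass).
#' @param total_co2 Optional total near-surface stock in Mg CO2/ha,
#'   overriding the stock-derived value.
#' @param loss Length-2 `c(min, max)` or length-3 `c(min, central, max)`
#'   loss fraction in (0, 1\]; a missing central defaults to the midpoint.
#' @param extent_family `"normal"` (truncated normal) or `"gamma"`
#'   (location-shifted gamma) for the extent distribution.
#' @param gamma_shape,gamma_scale Gamma parameters, required when
#'   `extent_family = "gamma"`.
#' @return A one-row tibble; bind rows to form the inputs table.
#' @examples
#' bc_ecosystem("mangrove",
#'   extent = c(13.8, 14.5, 15.2), rate = c(0.7, 1.9, 3.0),
#'   sediment_c = 280, biomass_c = 127, total_co2 = 1492
#' )
#' @export
bc_ecosystem <- function(ecosystem, extent, rate, sediment_c, biomass_c,
                         total_co2 = NA_real_, loss = c(0.25, 1),
                         extent_family = c("normal", "gamma"),
                         gamma_shape = NA_real_, gamma_scale = NA_real_) {
  extent_family <- match.arg(extent_family)
  stopifnot(
    is.character(ecosystem), length(ecosystem) == 1, nzchar(ecosystem),
    length(extent) == 3, length(rate) == 3
  )
  if (length(loss) == 2) loss <- c(loss[1], mean(loss), loss[2])
  stopifnot(length(loss) == 3)
  if (sediment_c < 0 || biomass_c < 0) {
    stop("bc_ecosystem: carbon stocks must be non-negative", call. = FALSE)
  }
  if (extent_family == "gamma" && (is.na(gamma_shape) || is.na(gamma_scale))) {
    stop("bc_ecosystem: gamma extent family needs gamma_shape and gamma_scale",
      call. = FALSE
    )
  }
  row <- tibble::tibble(
    ecosystem = ecosystem,
    extent_min = extent[1], extent_central = extent[2], extent_max = extent[3],
    extent_family = extent_family,
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    rate_min = rate[1], rate_central = rate[2], rate_max = rate[3],
    sediment_c = sediment_c, biomass_c = biomass_c, total_co2 = total_co2,
    loss_min = loss[1], loss_central = loss[2], loss_max = loss[3]
  )
  validate_inputs(row)
}

# Validates the inputs table; returns it invisibly unchanged on success.
validate_inputs <- function(inputs) {
  required <- c(
    "ecosystem", "extent_min", "extent_central", "extent_max", "extent_family",
    "gamma_shape", "gamma_scale", "rate_min", "rate_central", "rate_max",
    "sediment_c", "biomass_c", "total_co2", "loss_min", "loss_central",
    "loss_max"
  )
  missing <- setdiff(required, names(inputs))
  if (length(missing)) {
    stop("inputs table lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(inputs) < 1) stop("inputs table must have at least one row", call. = FALSE)
  if (anyDuplicated(inputs$ecosystem)) {
    stop("ecosystem names must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(inputs))) {
    r <- inputs[i, ]
    who <- r$ecosystem
    # quantity_range() enforces ordering/positivity per field
    tryCatch(
      {
        quantity_range(r$extent_min, r$extent_central, r$extent_max, "Mha")
        quantity_range(r$rate_min, r$rate_central, r$rate_max, "%/yr")
        quantity_range(r$loss_min, r$loss_central, r$loss_max, "fraction")
      },
      error = function(e) {
        stop(who, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    if (r$loss_min <= 0) stop(who, ": loss_min must be > 0", call. = FALSE)
    if (r$sediment_c < 0 || r$biomass_c < 0) {
      stop(who, ": carbon stocks must be non-negative", call. = FALSE)
    }
    if (r$extent_family == "gamma" &&
      (is.na(r$gamma_shape) || is.na(r$gamma_scale) ||
        r$gamma_shape <= 0 || r$gamma_scale <= 0)) {
      stop(who, ": gamma extent family needs positive gamma_shape/gamma_scale",
        call. = FALSE
      )
    }
    if (!r$extent_family %in% c("normal", "gamma")) {
      stop(who, ": unknown extent_family '", r$extent_family, "'", call. = FALSE)
    }
  }
  invisible(inputs)
}

# Total near-surface stock in Mg CO2/ha for one inputs row.
row_total_co2 <- function(row) {
  if (!is.na(row$total_co2)) {
    return(row$total_co2)
  }
  c_stock_to_co2(row$sediment_c + row$biomass_c)
}

# Calibrate the three factor distributions for one inputs row.
row_dists <- function(row, gamma_shift = TRUE, truncation = "range") {
  extent_range <- quantity_range(
    row$extent_min, row$extent_central, row$extent_max, "Mha"
  )
  extent <- if (row$extent_family == "gamma") {
    dist_shifted_gamma(extent_range, row$gamma_shape, row$gamma_scale,
      shift = gamma_shift
    )
  } else {
    dist_truncnorm(extent_range, truncation)
  }
  rate <- dist_truncnorm(
    quantity_range(row$rate_min, row$rate_central, row$rate_max, "%/yr"),
    truncation
  )
  loss <- quantity_range(row$loss_min, row$loss_central, row$loss_max, "fraction")
  density <- dist_truncnorm(
    susceptible_range(row_total_co2(row), loss),
    truncation
  )
  list(extent = extent, rate = rate, density = density)
}

# Deterministic 32-bit substream seed from (run seed, ecosystem name), so
# results do not depend on row order and streams differ across ecosystems.
bc_substream_seed <- function(seed, name) {
  m <- 2147483629
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer(((as.numeric(seed) %% m) + (h * 2654435) %% m) %% m)
}

#' Summarize draws to a nonparametric interval
#'
#' Empirical quantiles of the Monte Carlo output vector under the
#' linear-interpolation convention on order statistics
#' ([stats::quantile()] type 7), giving the lower bound, median, and upper
#' bound of the nonparametric confidence interval.
#'
#' @param x Nonempty numeric vector of draws.
#' @param percentiles Three strictly increasing probabilities in (0, 1);
#'   default `c(0.05, 0.5, 0.95)`, the 90% interval plus median.
#' @return Named numeric vector `c(lower, median, upper)`.
#' @examples
#' bc_summarize(1:100) # lower 5.95
#' @export
bc_summarize <- function(x, percentiles = c(0.05, 0.5, 0.95)) {
  if (!is.numeric(x) || length(x) == 0) {
    stop("bc_summarize: draws must be a nonempty numeric vector", call. = FALSE)
  }
  check_percentiles(percentiles)
  q <- stats::quantile(x, probs = percentiles, names = FALSE, type = 7)
  c(lower = q[1], median = q[2], upper = q[3])
}

check_percentiles <- function(p) {
  if (length(p) != 3 || any(p <= 0) || any(p >= 1) || any(diff(p) <= 0)) {
    stop("percentiles must be three strictly increasing values in (0, 1)",
      call. = FALSE
    )
  }
  invisible(p)
}

#' Run the Monte Carlo emissions pipeline
#'
#' For each ecosystem row the three factors are sampled independently
#' (`n_iterations` draws each, inverse-CDF, from a per-ecosystem RNG
#' substream derived from `seed` and the ecosystem name), per-iteration
#' emissions are formed with [emissions_point()], and the draws are
#' summarized to the median and the nonparametric interval. The global
#' total is aggregated across ecosystems by `aggregation`:
#' `"column_sum"` (default) sums each summary statistic across ecosystems —
#' the convention of published per-ecosystem tables — while
#' `"distribution_sum"` sums draws per iteration before summarizing, which
#' is the statistically coherent interval for the sum and is never wider.
#'
#' @param inputs Inputs table ([bc_ecosystem()] rows, [bc_table1()], or
#'   [synth_inputs()]).
#' @param n_iterations Number of Monte Carlo iterations (default 50000).
#' @param seed Integer seed; equal seeds give bit-identical results.
#' @param percentiles Three strictly increasing probabilities (default
#'   `c(0.05, 0.5, 0.95)`).
#' @param gamma_shift Shift gamma extent distributions to start at the
#'   reported minimum (default `TRUE`).
#' @param aggregation `"column_sum"` or `"distribution_sum"`.
#' @param truncation `"range"` truncates normals to the published range
#'   (default); `"zero"` truncates only below at zero.
#' @return A `bc_sim` object: list with `summary` (per-ecosystem tibble),
#'   `total` (one-row tibble), `draws` (long tibble of per-iteration
#'   extent/rate/density/emissions), and `config`.
#' @examples
#' sim <- bc_simulate(bc_table1(), n_iterations = 1000, seed = 7)
#' tidy(sim)
#' @export
bc_simulate <- function(inputs, n_iterations = 50000, seed = 1L,
                        percentiles = c(0.05, 0.5, 0.95),
                        gamma_shift = TRUE,
                        aggregation = c("column_sum", "distribution_sum"),
                        truncation = c("range", "zero")) {
  aggregation <- match.arg(aggregation)
  truncation <- match.arg(truncation)
  validate_inputs(inputs)
  dist_tbl <- tibble::tibble(
    ecosystem = inputs$ecosystem,
    dists = lapply(
      seq_len(nrow(inputs)),
      function(i) row_dists(inputs[i, ], gamma_shift, truncation)
    )
  )
  sim <- simulate_dists(dist_tbl, n_iterations, seed, percentiles, aggregation)
  sim$config$gamma_shift <- gamma_shift
  sim$config$truncation <- truncation
  sim$inputs <- inputs
  sim
}

#' Run the engine on explicit factor distributions
#'
#' Lower-level entry point taking calibrated `bc_dist` objects directly,
#' used by the lognormal oracle suite and available for custom factor
#' families.
#'
#' @param dist_tbl Tibble with columns `ecosystem` and `dists`, the latter
#'   a list column of `list(extent =, rate =, density =)` `bc_dist`
#'   objects.
#' @inheritParams bc_simulate
#' @return A `bc_sim` object.
#' @export
bc_simulate_dists <- function(dist_tbl, n_iterations = 50000, seed = 1L,
                              percentiles = c(0.05, 0.5, 0.95),
                              aggregation = c("column_sum", "distribution_sum")) {
  aggregation <- match.arg(aggregation)
  simulate_dists(dist_tbl, n_iterations, seed, percentiles, aggregation)
}

simulate_dists <- function(dist_tbl, n_iterations, seed, percentiles, aggregation) {
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("n_iterations must be >= 1", call. = FALSE)
  }
  n_iterations <- as.integer(n_iterations)
  check_percentiles(percentiles)
  seed <- as.integer(seed)

  draws <- purrr::map2(dist_tbl$ecosystem, dist_tbl$dists, function(name, d) {
    if (!all(c("extent", "rate", "density") %in% names(d))) {
      stop("factor distributions must be named extent, rate, density",
        call. = FALSE
      )
    }
    # private substream per ecosystem: reproducible regardless of row order
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(bc_substream_seed(seed, name))
    extent <- dist_sample(d$extent, n_iterations)
    rate <- dist_sample(d$rate, n_iterations)
    density <- dist_sample(d$density, n_iterations)
    tibble::tibble(
      ecosystem = name,
      iteration = seq_len(n_iterations),
      extent = extent, rate = rate, density = density,
      emissions = emissions_point(extent, rate, density)
    )
  }) |>
    dplyr::bind_rows()

  summary <- draws |>
    dplyr::group_by(.data$ecosystem) |>
    dplyr::summarise(
      lower = bc_summarize(.data$emissions, percentiles)[["lower"]],
      median = bc_summarize(.data$emissions, percentiles)[["median"]],
      upper = bc_summarize(.data$emissions, percentiles)[["upper"]],
      .groups = "drop"
    ) |>
    # preserve input row order, not alphabetical
    dplyr::arrange(match(.data$ecosystem, dist_tbl$ecosystem))

  structure(
    list(
      summary = summary,
      total = total_row(summary, draws, percentiles, aggregation),
      draws = draws,
      config = list(
        n_iterations = n_iterations, seed = seed,
        percentiles = percentiles, aggregation = aggregation
      )
    ),
    class = "bc_sim"
  )
}

total_row <- function(summary, draws, percentiles, aggregation) {
  if (aggregation == "column_sum") {
    tibble::tibble(
      ecosystem = "Total",
      lower = sum(summary$lower),
      median = sum(summary$median),
      upper = sum(summary$upper)
    )
  } else {
    total_draws <- draws |>
      dplyr::group_by(.data$iteration) |>
      dplyr::summarise(emissions = sum(.data$emissions), .groups = "drop")
    q <- bc_summarize(total_draws$emissions, percentiles)
    tibble::tibble(
      ecosystem = "Total",
      lower = q[["lower"]], median = q[["median"]], upper = q[["upper"]]
    )
  }
}

#' Re-aggregate a simulation's global total
#'
#' Recomputes the total row from retained draws under either aggregation
#' convention without resampling.
#'
#' @param sim A `bc_sim`.
#' @param aggregation `"column_sum"` or `"distribution_sum"`.
#' @return One-row tibble with `ecosystem = "Total"`.
#' @export
bc_total <- function(sim, aggregation = c("column_sum", "distribution_sum")) {
  stopifnot(inherits(sim, "bc_sim"))
  aggregation <- match.arg(aggregation)
  total_row(sim$summary, sim$draws, sim$config$percentiles, aggregation)
}

#' Per-iteration sum of emissions across ecosystems
#'
#' @param sim A `bc_sim`.
#' @return Numeric vector of length `n_iterations`.
#' @export
bc_total_draws <- function(sim) {
  stopifnot(inherits(sim, "bc_sim"))
  sim$draws |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(emissions = sum(.data$emissions), .groups = "drop") |>
    dplyr::pull(.data$emissions)
}

#' @export
print.bc_sim <- function(x, ...) {
  cat(sprintf(
    "<bc_sim> %d ecosystems, %d iterations, seed %d, %s total\n",
    nrow(x$summary), x$config$n_iterations, x$config$seed,
    x$config$aggregation
  ))
  print(tidy(x))
  invisible(x)
}

#' Tidy a simulation into its summary table
#'
#' @param x A `bc_sim`.
#' @param ... Unused.
#' @return Tibble with one row per ecosystem plus the Total row; columns
#'   `ecosystem`, `lower`, `median`, `upper` (Pg CO2/yr).
#' @method tidy bc_sim
#' @export
tidy.bc_sim <- function(x, ...) {
  dplyr::bind_rows(x$summary, x$total)
}

#' One-row overview of a simulation
#'
#' @param x A `bc_sim`.
#' @param ... Unused.
#' @return One-row tibble: total interval plus run settings.
#' @method glance bc_sim
#' @export
glance.bc_sim <- function(x, ...) {
  tibble::tibble(
    n_ecosystems = nrow(x$summary),
    n_iterations = x$config$n_iterations,
    seed = x$config$seed,
    aggregation = x$config$aggregation,
    total_lower = x$total$lower,
    total_median = x$total$median,
    total_upper = x$total$upper
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
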