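# Domain model: uncertainty ranges, ecosystem inputs, unit conversions.

#' Physical and unit constants
#'
#' `co2_per_c` is the molar-mass ratio of CO2 to carbon, computed as 44/12
#' (approximately 3.67). Per-hectare carbon stocks multiplied by this ratio
#' give potential CO2 emissions per hectare. The remaining constants chain
#' Mha x (%/yr) x (Mg/ha) into Pg/yr.
#'
#' @format A named list with elements `co2_per_c` (44/12), `mha_to_ha`
#'   (1e6), `mg_to_pg` (1e-9), and `percent_to_fraction` (1e-2).
#' @examples
#' round(bc_constants$co2_per_c, 2) # 3.67
#' @export
bc_constants <- list(
  co2_per_c = 44 / 12,
  mha_to_ha = 1e6,
  mg_to_pg = 1e-9,
  percent_to_fraction = 1e-2
)

#' Round half away from zero
#'
#' Commercial rounding: exact halves move away from zero, so 932.5 becomes
#' 933 and 18.45 becomes 18.5. Base [round()] uses round-half-to-even, which
#' would give 932 and 18.4; published summary tables are conventionally
#' rounded half-up, so report-facing numbers go through this helper.
#' Internal computation is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half-away-from-zero to `digits` decimals.
#' @examples
#' round_half_up(932.5) # 933
#' round_half_up(18.45, 1) # 18.5
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct a (minimum, central, maximum) quantity range
#'
#' An uncertain positive quantity summarized by its published minimum,
#' central estimate, and maximum. The central estimate need not be the
#' midpoint of the range.
#'
#' @param minimum,central,maximum Scalars with `minimum <= central <= maximum`.
#' @param units One of `"Mha"`, `"%/yr"`, `"Mg C/ha"`, `"Mg CO2/ha"`,
#'   `"fraction"`. Values must be strictly positive except for `"fraction"`,
#'   where they must lie in \[0, 1\].
#' @return A list of class `bc_range` with fields `minimum`, `central`,
#'   `maximum`, `units`.
#' @examples
#' quantity_range(13.8, 14.5, 15.2, "Mha")
#' @export
quantity_range <- function(minimum, central, maximum, units = "Mha") {
  units <- match.arg(units, c("Mha", "%/yr", "Mg C/ha", "Mg CO2/ha", "fraction"))
  vals <- c(minimum = minimum, central = central, maximum = maximum)
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("quantity_range: minimum, central, maximum must be numeric and non-missing",
      call. = FALSE
    )
  }
  if (!(minimum <= central && central <= maximum)) {
    stop("quantity_range: need minimum <= central <= maximum, got (",
      minimum, ", ", central, ", ", maximum, ")",
      call. = FALSE
    )
  }
  if (units == "fraction") {
    if (any(vals < 0) || any(vals > 1)) {
      stop("quantity_range: fraction values must lie in [0, 1]", call. = FALSE)
    }
  } else if (any(vals <= 0)) {
    stop("quantity_range: values must be positive for units '", units, "'",
      call. = FALSE
    )
  }
  structure(
    list(minimum = minimum, central = central, maximum = maximum, units = units),
    class = "bc_range"
  )
}

#' @export
print.bc_range <- function(x, ...) {
  cat(sprintf(
    "<bc_range> %g-%g (%g) %s\n",
    x$minimum, x$maximum, x$central, x$units
  ))
  invisible(x)
}

#' Convert a carbon stock to potential CO2 emissions
#'
#' Multiplies a per-hectare carbon stock by the CO2:C molar-mass ratio
#' (44/12), expressing the stock as the CO2 that would be emitted if it were
#' fully oxidized. `report = TRUE` additionally rounds half-away-from-zero
#' to the nearest integer for table display; computation downstream always
#' uses the unrounded value.
#'
#' @param stock_c Carbon stock in Mg C/ha (non-negative, vectorized).
#' @param report If `TRUE`, round to integer for display.
#' @return Potential emissions in Mg CO2/ha.
#' @examples
#' c_stock_to_co2(280) # 1026.67
#' c_stock_to_co2(280, report = TRUE) # 1027
#' @export
c_stock_to_co2 <- function(stock_c, report = FALSE) {
  stopifnot(is.numeric(stock_c))
  if (any(stock_c < 0)) {
    stop("c_stock_to_co2: carbon stock must be non-negative", call. = FALSE)
  }
  out <- stock_c * bc_constants$co2_per_c
  if (report) round_half_up(out) else out
}

#' Susceptible carbon range from a stock and loss-fraction bounds
#'
#' Of the near-surface carbon pool (vegetation biomass plus the top meter
#' of sediment), only a fraction is assumed emitted upon land-use
#' conversion — between 25% and 100% by default, with the midpoint 62.5%
#' as the central estimate. Scaling the total CO2-equivalent stock by these
#' bounds gives the susceptible-density range that enters the simulation.
#'
#' @param total_stock_co2 Total near-surface stock in Mg CO2/ha (positive
#'   scalar).
#' @param loss A `bc_range` with `units = "fraction"` and values in (0, 1\];
#'   default 0.25–1.0 with central 0.625.
#' @return A `bc_range` in Mg CO2/ha.
#' @examples
#' susceptible_range(1492) # 373-1492 (932.5) Mg CO2/ha
#' @export
susceptible_range <- function(total_stock_co2, loss = default_loss_fraction()) {
  stopifnot(is.numeric(total_stock_co2), length(total_stock_co2) == 1)
  if (total_stock_co2 <= 0) {
    stop("susceptible_range: total stock must be positive", call. = FALSE)
  }
  if (!inherits(loss, "bc_range") || loss$units != "fraction") {
    stop("susceptible_range: loss must be a bc_range with units 'fraction'",
      call. = FALSE
    )
  }
  if (loss$minimum <= 0 || loss$maximum > 1) {
    stop("susceptible_range: loss bounds must lie in (0, 1]", call. = FALSE)
  }
  quantity_range(
    loss$minimum * total_stock_co2,
    loss$central * total_stock_co2,
    loss$maximum * total_stock_co2,
    units = "Mg CO2/ha"
  )
}

#' Default loss-fraction range (25–100%, central 62.5%)
#'
#' @return A `bc_range` fraction with minimum 0.25, central 0.625, maximum 1.
#' @export
default_loss_fraction <- function() {
  quantity_range(0.25, 0.625, 1.0, units = "fraction")
}

#' Point emission estimate from extent, conversion rate, and density
#'
#' The deterministic core of the accounting model: annual emissions equal
#' global extent times the fraction of that extent converted per year times
#' the susceptible carbon density, with units chained from
#' Mha x (%/yr) x (Mg CO2/ha) into Pg CO2/yr. Linear in each argument.
#'
#' @param extent_mha Global extent in Mha.
#' @param rate_pct Conversion rate in percent of extent per year.
#' @param density_mg_ha Susceptible carbon density in Mg CO2/ha.
#' @return Emissions in Pg CO2/yr. Arguments recycle as in base arithmetic.
#' @examples
#' emissions_point(14.5, 1.9, 933) # 0.2570
#' @export
emissions_point <- function(extent_mha, rate_pct, density_mg_ha) {
  args <- list(extent_mha, rate_pct, density_mg_ha)
  if (!all(vapply(args, is.numeric, logical(1)))) {
    stop("emissions_point: all arguments must be numeric", call. = FALSE)
  }
  if (any(extent_mha < 0) || any(rate_pct < 0) || any(density_mg_ha < 0)) {
    stop("emissions_point: arguments must be non-negative", call. = FALSE)
  }
  extent_mha * bc_constants$mha_to_ha *
    (rate_pct * bc_constants$percent_to_fraction) *
    density_mg_ha * bc_constants$mg_to_pg
}
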