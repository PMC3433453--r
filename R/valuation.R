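# Economic valuation via the social cost of carbon, and flux comparisons.

#' Social cost of carbon defaults
#'
#' The marginal economic damage of one additional metric ton of CO2,
#' in 2007 US dollars: central estimate $41/Mg with a published range of
#' $7–81/Mg.
#'
#' @param low,central,high Dollars per Mg CO2, `0 < low <= central <= high`.
#' @return Named list with `low`, `central`, `high`, `dollar_year`.
#' @export
bc_scc <- function(low = 7, central = 41, high = 81) {
  if (!(low > 0 && low <= central && central <= high)) {
    stop("bc_scc: need 0 < low <= central <= high", call. = FALSE)
  }
  list(low = low, central = central, high = high, dollar_year = "2007 USD")
}

#' Reference CO2 fluxes for comparison
#'
#' Global annual emissions from deforestation (including freshwater
#' peatlands) and the continental-shelf ocean carbon sink, in Pg CO2/yr.
#'
#' @return Tibble with columns `name`, `value` (Pg CO2/yr).
#' @export
bc_references <- function() {
  tibble::tibble(
    name = c("deforestation", "shelf_sink"),
    value = c(5.5, 1.26)
  )
}

#' Economic damages from an emissions quantity
#'
#' Emissions in Pg CO2/yr times the social cost of carbon in $/Mg CO2 give
#' annual damages; since 1 Pg is one billion Mg, the product is directly in
#' billion dollars per year. Exactly linear in both arguments.
#'
#' @param emissions Emissions in Pg CO2/yr (non-negative, vectorized).
#' @param scc Social cost of carbon in $/Mg CO2 (positive).
#' @param report Round half-away-from-zero to one decimal for display.
#' @return Damages in billion USD/yr.
#' @examples
#' bc_damages(0.45, 41) # 18.45
#' bc_damages(0.45, 41, report = TRUE) # 18.5
#' @export
bc_damages <- function(emissions, scc, report = FALSE) {
  stopifnot(is.numeric(emissions), is.numeric(scc))
  if (any(emissions < 0)) {
    stop("bc_damages: emissions must be non-negative", call. = FALSE)
  }
  if (any(scc <= 0)) stop("bc_damages: scc must be positive", call. = FALSE)
  out <- emissions * scc
  if (report) round_half_up(out, 1) else out
}

#' Emissions as a percentage of a reference flux
#'
#' @param emissions Emissions in Pg CO2/yr.
#' @param reference Reference flux in Pg CO2/yr (positive).
#' @param report Round half-away-from-zero to integer percent.
#' @return Percent of the reference flux.
#' @examples
#' bc_compare(1.02, 5.5, report = TRUE) # 19
#' @export
bc_compare <- function(emissions, reference, report = FALSE) {
  stopifnot(is.numeric(emissions), is.numeric(reference))
  if (any(reference <= 0)) {
    stop("bc_compare: reference flux must be positive", call. = FALSE)
  }
  out <- 100 * emissions / reference
  if (report) round_half_up(out) else out
}

#' Value a simulation's emission statistics
#'
#' Applies the central social cost of carbon to the lower, median, and
#' upper emission statistics of each ecosystem and the total — so the
#' damage interval tracks the emissions interval, not the SCC range.
#' Damages are computed from unrounded emission statistics; pass the
#' result through the reporting rounder only at display time.
#'
#' @param sim A `bc_sim`.
#' @param scc A [bc_scc()] list (its `central` element is applied).
#' @return Tibble: `ecosystem`, emissions (`lower`, `median`, `upper`, Pg
#'   CO2/yr) and damages (`cost_lower`, `cost_median`, `cost_upper`,
#'   billion USD/yr).
#' @examples
#' sim <- bc_simulate(bc_table1(), n_iterations = 2000, seed = 3)
#' bc_valuation(sim)
#' @export
bc_valuation <- function(sim, scc = bc_scc()) {
  stopifnot(inherits(sim, "bc_sim"))
  tidy(sim) |>
    dplyr::mutate(
      cost_lower = bc_damages(.data$lower, scc$central),
      cost_median = bc_damages(.data$median, scc$central),
      cost_upper = bc_damages(.data$upper, scc$central)
    )
}
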