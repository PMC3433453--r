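# Configuration I/O, the packaged global input table, and result writers.

#' Packaged global input table
#'
#' The published per-ecosystem inputs: tidal marsh extent 2.2–40 (5.1) Mha
#' with gamma(1.6, 6) extent; mangrove 13.8–15.2 (14.5) Mha, all-normal;
#' seagrass 17.7–60 (30) Mha with gamma(4, 4); conversion rates 1–2 (1.5),
#' 0.7–3 (1.9), and 0.4–2.6 (1.5) %/yr; near-surface stocks of 949, 1492,
#' and 522 Mg CO2/ha subject to 25–100% loss.
#'
#' @return The inputs tibble for [bc_simulate()].
#' @examples
#' bc_table1()
#' @export
bc_table1 <- function() {
  bc_config()$inputs
}

#' Load the packaged default configuration
#'
#' @return The full parsed configuration (see [bc_config_read()]).
#' @export
bc_config <- function() {
  bc_config_read(
    system.file("extdata", "table1.yaml", package = "bluecarbon", mustWork = TRUE)
  )
}

cfg_field <- function(x, name, path, required = TRUE, default = NULL) {
  if (is.null(x[[name]])) {
    if (required) {
      stop("configuration error: missing field '", path, ".", name, "'",
        call. = FALSE
      )
    }
    return(default)
  }
  x[[name]]
}

#' Read a configuration file
#'
#' Parses and validates a YAML run configuration with top-level keys
#' `ecosystems` (each with `extent` \{min, central, max, family,
#' gamma_shape, gamma_scale\}, `rate` \{min, central, max\}, `stocks`
#' \{sediment_c, biomass_c, optional total_co2\}, and `loss` \{min, max,
#' optional central\}), `simulation` \{iterations, seed, percentiles,
#' gamma_shift, aggregation\}, `economics` \{scc_low, scc_central,
#' scc_high\}, and `references` (list of \{name, value\}). Violations are
#' reported with the offending field path.
#'
#' @param path Path to a YAML file.
#' @return A list of class `bc_config`: `inputs` (tibble), `simulation`
#'   (list), `scc` ([bc_scc()] list), `references` (tibble).
#' @export
bc_config_read <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: no such file: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(raw$ecosystems) || !length(raw$ecosystems)) {
    stop("configuration error: missing field 'ecosystems'", call. = FALSE)
  }
  rows <- lapply(names(raw$ecosystems), function(name) {
    e <- raw$ecosystems[[name]]
    p <- paste0("ecosystems.", name)
    ext <- cfg_field(e, "extent", p)
    rate <- cfg_field(e, "rate", p)
    stocks <- cfg_field(e, "stocks", p)
    loss <- cfg_field(e, "loss", p)
    family <- cfg_field(ext, "family", paste0(p, ".extent"),
      required = FALSE, default = "normal"
    )
    loss_vals <- c(
      cfg_field(loss, "min", paste0(p, ".loss")),
      cfg_field(loss, "central", paste0(p, ".loss"),
        required = FALSE, default = NA_real_
      ),
      cfg_field(loss, "max", paste0(p, ".loss"))
    )
    if (is.na(loss_vals[2])) loss_vals[2] <- mean(loss_vals[c(1, 3)])
    tryCatch(
      bc_ecosystem(
        ecosystem = name,
        extent = c(
          cfg_field(ext, "min", paste0(p, ".extent")),
          cfg_field(ext, "central", paste0(p, ".extent")),
          cfg_field(ext, "max", paste0(p, ".extent"))
        ),
        rate = c(
          cfg_field(rate, "min", paste0(p, ".rate")),
          cfg_field(rate, "central", paste0(p, ".rate")),
          cfg_field(rate, "max", paste0(p, ".rate"))
        ),
        sediment_c = cfg_field(stocks, "sediment_c", paste0(p, ".stocks")),
        biomass_c = cfg_field(stocks, "biomass_c", paste0(p, ".stocks")),
        total_co2 = cfg_field(stocks, "total_co2", paste0(p, ".stocks"),
          required = FALSE, default = NA_real_
        ),
        loss = loss_vals,
        extent_family = family,
        gamma_shape = cfg_field(ext, "gamma_shape", paste0(p, ".extent"),
          required = FALSE, default = NA_real_
        ),
        gamma_scale = cfg_field(ext, "gamma_scale", paste0(p, ".extent"),
          required = FALSE, default = NA_real_
        )
      ),
      error = function(err) {
        stop("configuration error in ", p, ": ", conditionMessage(err),
          call. = FALSE
        )
      }
    )
  })
  inputs <- dplyr::bind_rows(rows)

  simc <- raw$simulation %||% list()
  simulation <- list(
    iterations = cfg_field(simc, "iterations", "simulation",
      required = FALSE, default = 50000L
    ),
    seed = cfg_field(simc, "seed", "simulation", required = FALSE, default = 1L),
    percentiles = as.numeric(cfg_field(simc, "percentiles", "simulation",
      required = FALSE, default = c(0.05, 0.5, 0.95)
    )),
    gamma_shift = isTRUE(cfg_field(simc, "gamma_shift", "simulation",
      required = FALSE, default = TRUE
    )),
    aggregation = cfg_field(simc, "aggregation", "simulation",
      required = FALSE, default = "column_sum"
    )
  )
  check_percentiles(simulation$percentiles)
  if (!simulation$aggregation %in% c("column_sum", "distribution_sum")) {
    stop("configuration error: simulation.aggregation must be column_sum or ",
      "distribution_sum",
      call. = FALSE
    )
  }

  eco <- raw$economics %||% list()
  scc <- bc_scc(
    low = cfg_field(eco, "scc_low", "economics", required = FALSE, default = 7),
    central = cfg_field(eco, "scc_central", "economics",
      required = FALSE, default = 41
    ),
    high = cfg_field(eco, "scc_high", "economics", required = FALSE, default = 81)
  )

  refs <- raw$references %||% list()
  references <- if (length(refs)) {
    tibble::tibble(
      name = vapply(refs, function(r) cfg_field(r, "name", "references"), ""),
      value = vapply(
        refs, function(r) as.numeric(cfg_field(r, "value", "references")),
        numeric(1)
      )
    )
  } else {
    bc_references()
  }
  if (any(references$value <= 0)) {
    stop("configuration error: references.value must be positive", call. = FALSE)
  }

  structure(
    list(
      inputs = inputs, simulation = simulation,
      scc = scc, references = references
    ),
    class = "bc_config"
  )
}

#' Write a configuration back to YAML
#'
#' Inverse of [bc_config_read()]: a written configuration re-reads to an
#' equivalent object graph.
#'
#' @param config A `bc_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
bc_config_write <- function(config, path) {
  stopifnot(inherits(config, "bc_config"))
  ecosystems <- list()
  for (i in seq_len(nrow(config$inputs))) {
    r <- config$inputs[i, ]
    ext <- list(
      min = r$extent_min, central = r$extent_central, max = r$extent_max,
      family = r$extent_family
    )
    if (!is.na(r$gamma_shape)) ext$gamma_shape <- r$gamma_shape
    if (!is.na(r$gamma_scale)) ext$gamma_scale <- r$gamma_scale
    stocks <- list(sediment_c = r$sediment_c, biomass_c = r$biomass_c)
    if (!is.na(r$total_co2)) stocks$total_co2 <- r$total_co2
    ecosystems[[r$ecosystem]] <- list(
      extent = ext,
      rate = list(min = r$rate_min, central = r$rate_central, max = r$rate_max),
      stocks = stocks,
      loss = list(min = r$loss_min, central = r$loss_central, max = r$loss_max)
    )
  }
  out <- list(
    ecosystems = ecosystems,
    simulation = config$simulation,
    economics = list(
      scc_low = config$scc$low, scc_central = config$scc$central,
      scc_high = config$scc$high
    ),
    references = lapply(
      seq_len(nrow(config$references)),
      function(i) {
        list(
          name = config$references$name[i],
          value = config$references$value[i]
        )
      }
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Convenience wrapper: simulate, decompose uncertainty, and value, all
#' from one parsed configuration.
#'
#' @param config A `bc_config` (default: the packaged table).
#' @param ... Overrides passed to [bc_simulate()] (e.g. `n_iterations`,
#'   `seed`).
#' @return List with `sim` (`bc_sim`), `sensitivity`, `valuation`, and
#'   `comparisons` (total emissions vs each reference flux, in percent).
#' @examples
#' res <- bc_run(n_iterations = 2000, seed = 9)
#' res$valuation
#' @export
bc_run <- function(config = bc_config(), ...) {
  stopifnot(inherits(config, "bc_config"))
  args <- utils::modifyList(
    list(
      inputs = config$inputs,
      n_iterations = config$simulation$iterations,
      seed = config$simulation$seed,
      percentiles = config$simulation$percentiles,
      gamma_shift = config$simulation$gamma_shift,
      aggregation = config$simulation$aggregation
    ),
    list(...)
  )
  sim <- do.call(bc_simulate, args)
  comparisons <- config$references |>
    dplyr::mutate(
      pct_of_reference_lower = bc_compare(sim$total$lower, .data$value),
      pct_of_reference_upper = bc_compare(sim$total$upper, .data$value)
    )
  list(
    sim = sim,
    sensitivity = bc_sensitivity(sim),
    valuation = bc_valuation(sim, config$scc),
    comparisons = comparisons
  )
}

#' Write run results to disk
#'
#' Writes `results.csv` — the human-readable table (one row per ecosystem
#' plus Total; emissions rounded half-up to 2 decimals, damages to 1) —
#' and `results.json`, a machine-readable dump of the unrounded summary,
#' sensitivity, valuation, and a run manifest (seed, iterations,
#' percentiles, aggregation, package version, timestamp) sufficient to
#' reproduce every reported number. Optionally `draws.csv` with the raw
#' per-iteration draws.
#'
#' @param results A [bc_run()] result list (or a `bc_sim`, which is
#'   wrapped with default economics).
#' @param dir Output directory (created if needed).
#' @param draws Also write the raw draw table (default `FALSE`).
#' @return Invisibly, the paths written.
#' @export
bc_write_results <- function(results, dir, draws = FALSE) {
  if (inherits(results, "bc_sim")) {
    results <- list(
      sim = results,
      sensitivity = bc_sensitivity(results),
      valuation = bc_valuation(results),
      comparisons = NULL
    )
  }
  sim <- results$sim
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  human <- results$valuation |>
    dplyr::mutate(
      dplyr::across(c("lower", "median", "upper"), ~ round_half_up(.x, 2)),
      dplyr::across(dplyr::starts_with("cost_"), ~ round_half_up(.x, 1))
    )
  csv_path <- file.path(dir, "results.csv")
  utils::write.csv(human, csv_path, row.names = FALSE)

  dump <- list(
    manifest = list(
      package = "bluecarbon",
      version = as.character(utils::packageVersion("bluecarbon")),
      seed = sim$config$seed,
      n_iterations = sim$config$n_iterations,
      percentiles = sim$config$percentiles,
      aggregation = sim$config$aggregation,
      gamma_shift = sim$config$gamma_shift,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    summary = tidy(sim),
    valuation = results$valuation,
    sensitivity = as.data.frame(results$sensitivity),
    sensitivity_residual = attr(results$sensitivity, "residual"),
    comparisons = results$comparisons
  )
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(dump, json_path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )

  paths <- c(csv_path, json_path)
  if (draws) {
    draws_path <- file.path(dir, "draws.csv")
    utils::write.csv(sim$draws, draws_path, row.names = FALSE)
    paths <- c(paths, draws_path)
  }
  invisible(paths)
}
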