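# WTE demand trajectories and shortfall series.
#
# Demand compounds geometrically from a base-year WTE requirement; the
# default base of 20,935 WTE reflects the 2023 consultant establishment
# grossed up for the prevailing vacancy rate, and the default growth
# rates (1.8% medium, 2.4% high per year) extrapolate published
# demand-growth forecasts unchanged to the model horizon.

#' Demand configuration
#'
#' @param base_year Calendar year of the base demand (default 2023).
#' @param base_demand WTE demand in the base year (default 20935, > 0).
#' @param growth Annual proportional growth rate (>= -1); defaults to the
#'   medium scenario, 0.018 (the high scenario uses 0.024).
#' @param label Scenario label carried through to series.
#' @return An object of class `demand_config`.
#' @export
demand_config <- function(base_year = 2023L, base_demand = 20935,
                          growth = 0.018, label = "medium") {
  if (base_demand <= 0) {
    .phys_error("`base_demand` must be > 0", "physupply_validation_error")
  }
  if (growth < -1) {
    .phys_error("`growth` must be >= -1", "physupply_validation_error")
  }
  structure(list(base_year = as.integer(base_year),
                 base_demand = base_demand, growth = growth,
                 label = label),
            class = "demand_config")
}

#' Compounding WTE demand series
#'
#' `D(base_year + t) = base_demand * (1 + growth)^t` for
#' `t = 0 ... horizon`.
#'
#' @param config A [demand_config()].
#' @param horizon Number of years beyond the base year (>= 0).
#' @return data.frame with columns `year`, `demand`, `scenario`.
#' @examples
#' head(demand_series(demand_config(growth = 0.024, label = "high"), 25))
#' @export
demand_series <- function(config, horizon) {
  if (horizon < 0) {
    .phys_error("`horizon` must be >= 0", "physupply_validation_error")
  }
  t <- 0:horizon
  data.frame(year = config$base_year + t,
             demand = config$base_demand * (1 + config$growth)^t,
             scenario = config$label, stringsAsFactors = FALSE)
}

#' Shortfall of supply against demand
#'
#' Demand minus supply per year; negative values indicate oversupply.
#'
#' @param supply Either a `projection_result` or a data.frame with
#'   columns `year` and `wte`.
#' @param demand A demand series from [demand_series()].
#' @return data.frame with columns `year`, `shortfall`, `scenario`.
#' @export
shortfall <- function(supply, demand) {
  if (inherits(supply, "projection_result")) supply <- supply$supply
  if (!identical(as.integer(supply$year), as.integer(demand$year))) {
    .phys_error("supply and demand series cover different years",
                "physupply_alignment_error")
  }
  data.frame(year = demand$year, shortfall = demand$demand - supply$wte,
             scenario = demand$scenario, stringsAsFactors = FALSE)
}

#' Base demand from current supply and a vacancy-style shortfall rate
#'
#' Helpers for deriving a base-year demand from the base-year supply and
#' an initial shortfall rate `s`.  Two conventions are in use: grossing
#' up (`supply / (1 - s)`, i.e. the shortfall is a fraction of demand)
#' and marking up (`supply * (1 + s)`, i.e. a fraction of supply).
#' Neither is asserted as canonical; the packaged default configuration
#' takes base demand directly as a number instead.
#'
#' @param supply_wte Base-year supply (WTE).
#' @param shortfall_rate Initial shortfall rate (default 0.054).
#' @param method `"grossup"` or `"markup"`.
#' @return Base-year demand (WTE).
#' @export
demand_from_supply <- function(supply_wte, shortfall_rate = 0.054,
                               method = c("grossup", "markup")) {
  method <- match.arg(method)
  if (shortfall_rate < 0 || shortfall_rate >= 1) {
    .phys_error("`shortfall_rate` must lie in [0, 1)",
                "physupply_validation_error")
  }
  switch(method,
         grossup = supply_wte / (1 - shortfall_rate),
         markup = supply_wte * (1 + shortfall_rate))
}
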