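# Deterministic sensitivity machinery: one-way (tornado) analysis,
# horizon sweeps, and biosimilar pricing scenarios.

# Deterministic paired run at given base values; returns cea_comparison.
deterministic_comparison <- function(ledg, settings, life_table,
                                     strategies = NULL,
                                     wac_schedule = NULL) {
  if (is.null(strategies)) {
    strategies <- strategy_pair(settings$induction_cycles)
  }
  params <- base_case_parameters(ledg)
  st <- effective_settings(params, settings)
  res_e <- run_strategy(strategies$early, params, st, life_table,
                        wac_schedule)
  res_d <- run_strategy(strategies$delayed, params, st, life_table,
                        wac_schedule)
  compare_strategies(res_e, res_d, st$wtp)
}

#' One-way deterministic sensitivity analysis for a parameter
#'
#' Runs the full deterministic model with the named parameter at its low
#' and high bound (all other parameters at base) and records the
#' incremental net monetary benefit at each setting.
#'
#' @param ledg A `cea_ledger`.
#' @param parameter Name of a ledger parameter with bounds.
#' @param settings A `cea_settings` list.
#' @param life_table Life-table data frame.
#' @return A one-row data frame: `parameter`, `low`, `high`, `inmb_low`,
#'   `inmb_high`, `width`.
#' @export
one_way <- function(ledg, parameter, settings, life_table) {
  sp <- ledg$specs[[parameter]]
  if (is.null(sp)) stop("unknown parameter '", parameter, "'",
                        call. = FALSE)
  at <- function(v) {
    deterministic_comparison(set_base_values(ledg, stats::setNames(v, parameter),
                                             relabel = FALSE),
                             settings, life_table)$inmb
  }
  inmb_low <- at(sp$low)
  inmb_high <- at(sp$high)
  data.frame(parameter = parameter, low = sp$low, high = sp$high,
             inmb_low = inmb_low, inmb_high = inmb_high,
             width = abs(inmb_high - inmb_low), stringsAsFactors = FALSE)
}

#' Tornado report
#'
#' @param entries Data frame of [one_way()] rows (>= 1), or a list of them.
#' @return The entries sorted by descending bar width, ties broken by
#'   parameter name.
#' @export
tornado <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries)) {
    entries <- do.call(rbind, entries)
  }
  if (!nrow(entries)) stop("no tornado entries", call. = FALSE)
  entries[order(-entries$width, entries$parameter), , drop = FALSE]
}

#' Full tornado analysis over every bounded ledger parameter
#'
#' @param ledg A `cea_ledger`.
#' @param settings A `cea_settings` list.
#' @param life_table Life-table data frame.
#' @param parameters Parameters to vary (default: every ledger entry whose
#'   bounds are not degenerate).
#' @return Sorted tornado data frame.
#' @export
tornado_analysis <- function(ledg, settings, life_table,
                             parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- names(Filter(function(sp) sp$low < sp$high, ledg$specs))
  }
  tornado(lapply(parameters, function(p)
    one_way(ledg, p, settings, life_table)))
}

#' Incremental net monetary benefit across analytic horizons
#'
#' One full deterministic paired run per horizon, each with its own
#' discounted totals.
#'
#' @param ledg A `cea_ledger`.
#' @param settings A `cea_settings` list (horizon overridden per run).
#' @param life_table Life-table data frame.
#' @param years Integer vector of horizons (each >= 1).
#' @return Data frame: `horizon_years`, `delta_cost`, `delta_qaly`, `inmb`.
#' @export
horizon_sweep <- function(ledg, settings, life_table, years = 1:25) {
  stopifnot(all(years >= 1))
  rows <- lapply(years, function(y) {
    st <- settings
    st$horizon_years <- y
    cmp <- deterministic_comparison(ledg, st, life_table)
    data.frame(horizon_years = y, delta_cost = cmp$delta_cost,
               delta_qaly = cmp$delta_qaly, inmb = cmp$inmb)
  })
  do.call(rbind, rows)
}

#' Scenario specification
#'
#' @param id Scenario identifier.
#' @param description Free text.
#' @param wac_multiplier Price multiplier in (0, 1] applied to both
#'   biologics' wholesale acquisition costs.
#' @param start_year Model year from which the multiplier applies
#'   (0 = from launch).
#' @param horizon_years Optional horizon override.
#' @return A `cea_scenario`.
#' @export
scenario_spec <- function(id, description = "", wac_multiplier = 1,
                          start_year = 0, horizon_years = NULL) {
  if (wac_multiplier <= 0 || wac_multiplier > 1) {
    stop("wac_multiplier must be in (0, 1]", call. = FALSE)
  }
  structure(list(id = id, description = description,
                 wac_multiplier = wac_multiplier, start_year = start_year,
                 horizon_years = horizon_years), class = "cea_scenario")
}

#' Biosimilar pricing scenario
#'
#' Scales drug-acquisition unit costs of both biologics by the scenario's
#' multiplier from its entry year onward, leaves every efficacy, utility
#' and secondary-cost parameter untouched, and runs the full deterministic
#' comparison.
#'
#' @param ledg A `cea_ledger`.
#' @param spec A `cea_scenario`.
#' @param settings A `cea_settings` list.
#' @param life_table Life-table data frame.
#' @return A `cea_comparison`.
#' @export
biosimilar_scenario <- function(ledg, spec, settings, life_table) {
  stopifnot(inherits(spec, "cea_scenario"))
  st <- settings
  if (!is.null(spec$horizon_years)) st$horizon_years <- spec$horizon_years
  deterministic_comparison(
    ledg, st, life_table,
    wac_schedule = list(multiplier = spec$wac_multiplier,
                        start_year = spec$start_year))
}

#' The default pricing scenarios
#'
#' Two biosimilar substitution scenarios (15% and 60% WAC discounts from
#' launch) and two hypothetical market-entry scenarios applying a synthetic
#' post-biosimilar price-erosion multiplier from year 1 and year 5.
#'
#' @param ledg A `cea_ledger` supplying the discount and erosion
#'   parameters.
#' @return Named list of `cea_scenario` objects.
#' @export
default_scenarios <- function(ledg) {
  v <- base_values(ledg)
  list(
    substitution_15 = scenario_spec(
      "substitution_15", "biosimilar substitution, 15% WAC discount",
      wac_multiplier = 1 - v[["biosim_discount_small"]]),
    substitution_60 = scenario_spec(
      "substitution_60", "biosimilar substitution, 60% WAC discount",
      wac_multiplier = 1 - v[["biosim_discount_large"]]),
    entry_year1 = scenario_spec(
      "entry_year1", "biosimilar market entry at year 1 (price erosion)",
      wac_multiplier = v[["biosim_erosion_multiplier"]], start_year = 1),
    entry_year5 = scenario_spec(
      "entry_year5", "biosimilar market entry at year 5 (price erosion)",
      wac_multiplier = v[["biosim_erosion_multiplier"]], start_year = 5))
}
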