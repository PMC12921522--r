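# Valuation layer: per-cycle utilities (EQ-5D with glucocorticoid-dose
# decrement) and costs (weight-based drug acquisition plus state-stratified
# secondary costs), accumulated with annual discounting.

eq5d_floor <- -0.594

#' Discount factor at a cycle
#'
#' `(1 + annual_rate)^(-cycle / cycles_per_year)`.
#'
#' @param annual_rate Annual discount rate (>= 0).
#' @param cycle Cycle index (0-based).
#' @param cycles_per_year Cycles per year.
#' @return Discount factor in (0, 1].
#' @export
discount_factor <- function(annual_rate, cycle, cycles_per_year = 12L) {
  stopifnot(annual_rate >= 0)
  (1 + annual_rate)^(-cycle / cycles_per_year)
}

#' Utility model from a parameter set
#'
#' State utilities are anchored at the complete-response level with
#' strictly positive decrements for partial response and nonresponse, so
#' the ordering nonresponse <= partial <= complete holds for every draw.
#' A common multiplicative time trend (piecewise-constant anchors from a
#' longitudinal incident-cohort EQ-5D trajectory) applies to all states.
#'
#' @param params A `cea_parameter_set`.
#' @return A `cea_utility_model`.
#' @export
utility_model <- function(params) {
  u_cr <- pv(params, "u_complete")
  base <- c(pretreatment_bel = pv(params, "u_pretreatment"),
            complete_bel = u_cr,
            partial_bel = u_cr - pv(params, "u_gap_partial"),
            nonresponse_bel = u_cr - pv(params, "u_gap_partial") -
              pv(params, "u_gap_nonresponse"),
            no_treatment = pv(params, "u_no_treatment"))
  base[c("complete_ani", "partial_ani", "nonresponse_ani")] <-
    base[c("complete_bel", "partial_bel", "nonresponse_bel")]
  structure(list(
    base = base,
    trend = function(year) pv_at(params, "u_trend", year),
    steroid_decrement_per_mg = pv(params, "steroid_decrement")),
    class = "cea_utility_model")
}

#' Prednisone-dose trajectory from a parameter set
#'
#' Per-state prednisone-equivalent maintenance doses (mg/day), plus the
#' early arm's higher baseline dose applied in the pretreatment state.
#'
#' @param params A `cea_parameter_set`.
#' @return A `cea_steroid_trajectory`.
#' @export
steroid_trajectory <- function(params) {
  dose <- c(pretreatment_bel = pv(params, "pred_dose_pretreatment"),
            complete_bel = pv(params, "pred_dose_complete"),
            partial_bel = pv(params, "pred_dose_partial"),
            nonresponse_bel = pv(params, "pred_dose_nonresponse"),
            no_treatment = pv(params, "pred_dose_no_treatment"))
  dose[c("complete_ani", "partial_ani", "nonresponse_ani")] <-
    dose[c("complete_bel", "partial_bel", "nonresponse_bel")]
  if (any(dose < 0)) stop("prednisone doses must be >= 0", call. = FALSE)
  structure(list(dose = dose,
                 early_offset = pv(params, "pred_offset_early"),
                 reference_dose = pv(params, "pred_dose_reference")),
            class = "cea_steroid_trajectory")
}

# Dose in a given internal state under a strategy (mg/day prednisone
# equivalent). The early arm's baseline offset applies while untreated-
# by-response, i.e. in the pretreatment state.
state_dose <- function(steroid, state, strategy) {
  d <- steroid$dose[[state]]
  if (strategy$pred_offset_applied && state == "pretreatment_bel") {
    d <- d + steroid$early_offset
  }
  d
}

#' State utility at a cycle
#'
#' Baseline state utility times the time trend, minus the glucocorticoid
#' decrement (`steroid_decrement_per_mg` EQ-5D per mg/day of prednisone
#' equivalent above the reference dose), clamped to the EQ-5D range
#' \[-0.594, 1\]. Identical across strategies for the same state and dose.
#'
#' @param um A `cea_utility_model`.
#' @param steroid A `cea_steroid_trajectory`.
#' @param state An internal living state name.
#' @param strategy A `cea_strategy`.
#' @param cycle Cycle index (0-based).
#' @param cycles_per_year Cycles per year.
#' @return EQ-5D utility.
#' @export
state_utility_at <- function(um, steroid, state, strategy, cycle,
                             cycles_per_year = 12L) {
  stopifnot(state %in% internal_states, state != "death")
  u <- um$base[[state]] * um$trend(cycle / cycles_per_year)
  dose <- state_dose(steroid, state, strategy)
  u <- u - um$steroid_decrement_per_mg * (dose - steroid$reference_dose)
  min(max(u, eq5d_floor), 1)
}

#' Cost model from a parameter set
#'
#' Drug acquisition uses wholesale acquisition cost (WAC) per vial with
#' whole-vial wastage; belimumab is dosed 10 mg/kg (400 mg vials) every 4
#' weeks after loading doses at weeks 0 and 2, anifrolumab 300 mg (one
#' vial) every 4 weeks. The 4-week schedule is mapped onto monthly cycles
#' at 13/12 infusions per month in expectation; the first model month
#' carries the two loading doses. Secondary (non-drug) monthly costs are
#' stratified by health state with a piecewise-constant time trend.
#'
#' @param params A `cea_parameter_set`.
#' @return A `cea_cost_model`.
#' @export
cost_model <- function(params) {
  secondary <- c(pretreatment_bel = pv(params, "cost_pre"),
                 complete_bel = pv(params, "cost_cr"),
                 partial_bel = pv(params, "cost_pr"),
                 nonresponse_bel = pv(params, "cost_nr"),
                 no_treatment = pv(params, "cost_off"))
  # secondary costs assumed equivalent across biologics
  secondary[c("complete_ani", "partial_ani", "nonresponse_ani")] <-
    secondary[c("complete_bel", "partial_bel", "nonresponse_bel")]
  if (any(secondary < 0)) stop("secondary costs must be >= 0", call. = FALSE)
  structure(list(
    wac_belimumab_vial = pv(params, "wac_belimumab_vial"),
    wac_anifrolumab_vial = pv(params, "wac_anifrolumab_vial"),
    biologic_cost_scalar = pv(params, "biologic_cost_scalar"),
    patient_weight_kg = pv(params, "patient_weight_kg"),
    secondary = secondary,
    cost_trend = function(year) pv_at(params, "cost_trend", year)),
    class = "cea_cost_model")
}

#' Drug acquisition cost for one cycle
#'
#' @param cm A `cea_cost_model`.
#' @param context `"belimumab"`, `"anifrolumab"` or `"off_treatment"`.
#' @param cycle Model month (1-based: month 1 is the loading month).
#' @param patient_weight_kg Body weight for weight-based dosing.
#' @param wac_multiplier Price multiplier (biosimilar scenarios), default 1.
#' @return Cost in 2024 USD for the cycle.
#' @export
drug_cost_per_cycle <- function(cm, context, cycle,
                                patient_weight_kg = cm$patient_weight_kg,
                                wac_multiplier = 1) {
  if (context == "off_treatment") return(0)
  infusions <- if (cycle <= 1L) 2 else 13 / 12
  if (context == "belimumab") {
    stopifnot(patient_weight_kg > 0)
    vials <- ceiling(10 * patient_weight_kg / 400)
    vials * cm$wac_belimumab_vial * wac_multiplier * cm$biologic_cost_scalar *
      infusions
  } else if (context == "anifrolumab") {
    cm$wac_anifrolumab_vial * wac_multiplier * cm$biologic_cost_scalar *
      infusions
  } else {
    stop("unknown drug context '", context, "'", call. = FALSE)
  }
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Beginning-of-cycle convention without half-cycle correction (the
#' optional correction averages adjacent occupancy rows): month `k` is
#' valued with the occupancy at row `k - 1`, discounted at
#' `(1 + r)^(-(k - 1) / 12)`. QALYs credit each living state's utility for
#' 1/12 year; death contributes zero utility and zero cost.
#'
#' @param trace A `cea_trace`.
#' @param um A `cea_utility_model`.
#' @param cm A `cea_cost_model`.
#' @param steroid A `cea_steroid_trajectory`.
#' @param strategy The `cea_strategy` the trace was run under.
#' @param settings An `cea_settings` list.
#' @param wac_schedule Optional biosimilar price schedule:
#'   `list(multiplier =, start_year =)` applied to both biologics' WACs
#'   from the given model year onward.
#' @return A `cea_strategy_result` with discounted and undiscounted totals
#'   and a per-cycle audit data frame.
#' @export
accumulate <- function(trace, um, cm, steroid, strategy, settings,
                       wac_schedule = NULL) {
  n_rows <- nrow(trace) - 1L  # months valued: 1..n_rows
  cpy <- settings$cycles_per_year
  if (n_rows < 1L) {
    res <- list(cost = 0, qaly = 0, cost_undiscounted = 0,
                qaly_undiscounted = 0, strategy = strategy$label,
                audit = data.frame())
    return(structure(res, class = "cea_strategy_result"))
  }
  months <- seq_len(n_rows)
  years <- (months - 1L) / cpy
  liv <- internal_states[1:8]

  # per-cycle utility matrix (months x living states)
  trend <- um$trend(years)
  dose <- vapply(liv, function(s) state_dose(steroid, s, strategy),
                 numeric(1))
  pen <- um$steroid_decrement_per_mg * (dose - steroid$reference_dose)
  U <- outer(trend, um$base[liv]) -
    matrix(pen, n_rows, 8L, byrow = TRUE)
  U <- pmin(pmax(U, eq5d_floor), 1)

  # per-cycle drug costs: closed-form equivalent of drug_cost_per_cycle
  # (pointwise agreement asserted in tests)
  wac_mult <- rep(1, n_rows)
  if (!is.null(wac_schedule)) {
    stopifnot(wac_schedule$multiplier > 0, wac_schedule$multiplier <= 1)
    wac_mult[years >= wac_schedule$start_year] <- wac_schedule$multiplier
  }
  infusions <- ifelse(months <= 1L, 2, 13 / 12)
  unit <- c(belimumab = ceiling(10 * cm$patient_weight_kg / 400) *
              cm$wac_belimumab_vial * cm$biologic_cost_scalar,
            anifrolumab = cm$wac_anifrolumab_vial * cm$biologic_cost_scalar,
            off_treatment = 0)
  drug <- (infusions * wac_mult) %o% unit[state_drug_context[liv]]
  colnames(drug) <- liv
  ctrend <- cm$cost_trend(years)
  Csec <- outer(ctrend, cm$secondary[liv])
  C <- drug + Csec

  occ <- trace[months, liv, drop = FALSE]
  if (isTRUE(settings$half_cycle_correction)) {
    occ <- (occ + trace[months + 1L, liv, drop = FALSE]) / 2
  }
  qaly_cycle <- rowSums(occ * U) / cpy
  cost_cycle <- rowSums(occ * C)
  disc <- discount_factor(settings$discount_rate, months - 1L, cpy)

  audit <- data.frame(cycle = months, discount = disc,
                      cost = cost_cycle, qaly = qaly_cycle,
                      cost_discounted = cost_cycle * disc,
                      qaly_discounted = qaly_cycle * disc)
  structure(list(cost = sum(audit$cost_discounted),
                 qaly = sum(audit$qaly_discounted),
                 cost_undiscounted = sum(cost_cycle),
                 qaly_undiscounted = sum(qaly_cycle),
                 strategy = strategy$label, audit = audit),
            class = "cea_strategy_result")
}

#' @export
print.cea_strategy_result <- function(x, ...) {
  cat(sprintf("<cea_strategy_result> %s: cost $%.2f, %.4f QALYs (discounted)\n",
              x$strategy, x$cost, x$qaly))
  invisible(x)
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate()].
#'
#' @inheritParams run_cohort
#' @param wac_schedule Optional biosimilar price schedule (see
#'   [accumulate()]).
#' @return A `cea_strategy_result`.
#' @export
run_strategy <- function(strategy, params, settings, life_table,
                         wac_schedule = NULL) {
  trace <- run_cohort(strategy, params, settings, life_table)
  accumulate(trace, utility_model(params), cost_model(params),
             steroid_trajectory(params), strategy, settings, wac_schedule)
}
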