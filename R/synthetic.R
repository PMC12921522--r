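# Synthetic inputs: a Gompertz-Makeham life table standing in for a US
# life table, a complete default parameter ledger emulating the structure
# of a literature-derived parameter table, and a calibration routine that
# pins four free parameters to the published base-case totals.

#' Synthetic life-table specification
#'
#' Gompertz-Makeham mortality per sex:
#' `qx(age) = 1 - exp(-(makeham + scale * exp(shape * age)))`.
#' The default parameters give adult mortality of US-like magnitude with
#' female rates below male rates at every age.
#'
#' @param female,male Lists with `makeham`, `scale`, `shape`.
#' @param age_range Two-element integer vector of covered ages.
#' @return A `cea_life_table_spec`.
#' @export
life_table_spec <- function(
    female = list(makeham = 1.0e-4, scale = 2.0e-5, shape = 0.095),
    male = list(makeham = 2.0e-4, scale = 3.5e-5, shape = 0.090),
    age_range = c(0L, 100L)) {
  for (p in list(female, male)) {
    stopifnot(p$makeham > 0, p$scale > 0, p$shape >= 0)
  }
  structure(list(female = female, male = male, age_range = age_range),
            class = "cea_life_table_spec")
}

#' Generate a synthetic life table
#'
#' @param spec A `cea_life_table_spec`.
#' @return Life-table data frame (`age`, `sex`, `qx`) covering both sexes
#'   over the spec's age range; any qx above 1 is clipped with a warning.
#' @export
generate_life_table <- function(spec = life_table_spec()) {
  ages <- seq(spec$age_range[1L], spec$age_range[2L])
  rows <- lapply(c("female", "male"), function(s) {
    p <- spec[[s]]
    qx <- 1 - exp(-(p$makeham + p$scale * exp(p$shape * ages)))
    if (any(qx > 1)) {
      warning("life-table qx clipped at 1 for sex ", s)
      qx <- pmin(qx, 1)
    }
    data.frame(age = ages, sex = s, qx = qx, stringsAsFactors = FALSE)
  })
  lt <- do.call(rbind, rows)
  validate_life_table(lt)
  lt
}

#' Write a life table to CSV
#'
#' @param lt Life-table data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  validate_life_table(lt)
  utils::write.csv(lt, path, row.names = FALSE)
  invisible(path)
}

#' Parameter names the engine requires
#'
#' Enumerated from code (the same accessors the engine calls), so the
#' required set given to [validate_ledger()] cannot drift from the engine.
#'
#' @return Character vector of required ledger parameter names.
#' @export
required_parameters <- function() {
  c(
    # induction response split and early-arm effect
    "p_induction_cr", "p_induction_pr", "or_sri4_early",
    # monthly disease transitions
    "p_cr_to_pr", "p_pr_to_cr", "p_pr_to_nr", "p_nr_to_pr",
    "p_nr_restart", "p_nr_stop", "p_nr_switch",
    "p_off_flare", "p_ani_cr", "p_ani_pr", "ani_attenuation",
    "p_nr_ani_stop",
    # mortality
    "smr_f_young", "smr_f_mid", "smr_f_old",
    "smr_m_young", "smr_m_mid", "smr_m_old", "smr_multiplier",
    # utilities and glucocorticoid burden
    "u_complete", "u_gap_partial", "u_gap_nonresponse",
    "u_pretreatment", "u_no_treatment", "u_trend",
    "steroid_decrement", "pred_dose_pretreatment", "pred_dose_complete",
    "pred_dose_partial", "pred_dose_nonresponse", "pred_dose_no_treatment",
    "pred_dose_reference", "pred_offset_early",
    # costs
    "wac_belimumab_vial", "wac_anifrolumab_vial", "patient_weight_kg",
    "biologic_cost_scalar", "cost_pre", "cost_cr", "cost_pr", "cost_nr",
    "cost_off", "cost_trend",
    # economics and scenarios
    "wtp", "discount_rate",
    "biosim_discount_small", "biosim_discount_large",
    "biosim_erosion_multiplier")
}

#' Generate the default parameter ledger
#'
#' A complete ledger covering every engine-required parameter. Values
#' printed in the source analysis (3% discount rate, $50,000/QALY
#' willingness-to-pay, the -0.005/mg prednisone EQ-5D decrement, the
#' 1.08-3.47 SRI-4 odds-ratio range, the 15%/60% biosimilar discounts, the
#' early arm's +10 mg/day baseline prednisone) are set exactly and
#' labelled `"printed"`. All other values are synthetic stand-ins of
#' plausible clinical magnitude, labelled `"synthetic"` or
#' `"synthetic-calibrated"` where [calibrate_to_base_case()] has pinned
#' them to the published base-case totals.
#'
#' @param seed Unused (the ledger is deterministic); kept for interface
#'   stability.
#' @return A `cea_ledger` passing [validate_ledger()].
#' @export
generate_default_ledger <- function(seed = NULL) {
  p <- param_spec  # local alias for brevity
  specs <- list(
    # --- induction response split (delayed-arm baseline) ---
    p("p_induction_cr", "probability", 0.30, 0.15, 0.60,
      dist = dist_spec("beta", se = 0.04), units = "probability",
      provenance = "synthetic; real-world SRI-4 response at end of induction, delayed arm"),
    p("p_induction_pr", "probability", 0.40, 0.25, 0.55,
      dist = dist_spec("beta", se = 0.04), units = "probability",
      provenance = "synthetic; partial response (improved, SRI-4 not met) at end of induction"),
    p("or_sri4_early", "odds_ratio", 2.66007531617154, 1.08, 3.47,
      dist = dist_spec("lognormal", se = 0.45), units = "odds ratio",
      provenance = "bounds printed (1.08-3.47); base value synthetic-calibrated within the printed range",
      label = "synthetic-calibrated"),
    # --- monthly disease transitions ---
    p("p_cr_to_pr", "probability", 0.002, dist = dist_spec("beta", se = 0.0005),
      units = "monthly probability",
      provenance = "synthetic; loss of complete response, long-term continuation data"),
    p("p_pr_to_cr", "probability", 0.006, dist = dist_spec("beta", se = 0.0015),
      units = "monthly probability",
      provenance = "synthetic; late attainment of SRI-4 among partial responders"),
    p("p_pr_to_nr", "probability", 0.005, dist = dist_spec("beta", se = 0.0012),
      units = "monthly probability",
      provenance = "synthetic; deterioration of partial responders"),
    p("p_nr_to_pr", "probability", 0.002, dist = dist_spec("beta", se = 0.0005),
      units = "monthly probability",
      provenance = "synthetic; spontaneous improvement of nonresponders on treatment"),
    p("p_nr_restart", "probability", 0.060, dist = dist_spec("beta", se = 0.012),
      units = "monthly probability",
      provenance = "synthetic; re-induction after discontinuation for inefficacy"),
    p("p_nr_stop", "probability", 0.004, dist = dist_spec("beta", se = 0.001),
      units = "monthly probability",
      provenance = "synthetic; discontinuation to no-treatment (inefficacy/adverse events)"),
    p("p_nr_switch", "probability", 0.006, dist = dist_spec("beta", se = 0.0015),
      units = "monthly probability",
      provenance = "synthetic; switch to anifrolumab after belimumab failure"),
    p("p_off_flare", "probability", 0.060, dist = dist_spec("beta", se = 0.012),
      units = "monthly probability",
      provenance = "synthetic; severe flare off treatment (post-withdrawal outcomes)"),
    p("p_ani_cr", "probability", 0.40, dist = dist_spec("beta", se = 0.05),
      units = "probability",
      provenance = "synthetic; anifrolumab response (pooled phase III), biologic-naive"),
    p("p_ani_pr", "probability", 0.30, dist = dist_spec("beta", se = 0.05),
      units = "probability",
      provenance = "synthetic; anifrolumab partial response (pooled phase III)"),
    p("ani_attenuation", "probability", 0.75, 0.50, 1.00,
      dist = dist_spec("beta", se = 0.08), units = "multiplier on response probabilities",
      provenance = "synthetic; attenuation for biologic-experienced patients (post hoc trial analysis)"),
    p("p_nr_ani_stop", "probability", 0.020, dist = dist_spec("beta", se = 0.004),
      units = "monthly probability",
      provenance = "synthetic; anifrolumab discontinuation to no-treatment"),
    # --- mortality: SMR bands (Italian SLE cohort pattern) ---
    p("smr_f_young", "continuous", 3.0, units = "SMR",
      provenance = "synthetic; female SMR, age < 40"),
    p("smr_f_mid", "continuous", 2.0, units = "SMR",
      provenance = "synthetic; female SMR, age 40-59"),
    p("smr_f_old", "continuous", 1.4, units = "SMR",
      provenance = "synthetic; female SMR, age >= 60"),
    p("smr_m_young", "continuous", 2.4, units = "SMR",
      provenance = "synthetic; male SMR, age < 40"),
    p("smr_m_mid", "continuous", 1.8, units = "SMR",
      provenance = "synthetic; male SMR, age 40-59"),
    p("smr_m_old", "continuous", 1.3, units = "SMR",
      provenance = "synthetic; male SMR, age >= 60"),
    p("smr_multiplier", "cost", 1.0, 0.7, 1.3,
      dist = dist_spec("lognormal", se = 0.15), units = "multiplier",
      provenance = "synthetic; joint SMR uncertainty (log-normal); life table held fixed in PSA"),
    # --- utilities ---
    p("u_complete", "utility", 0.699284908853546, 0.60, 0.95,
      dist = dist_spec("beta", se = 0.02), units = "EQ-5D",
      provenance = "synthetic-calibrated; complete-response (SRI-4) utility anchor",
      label = "synthetic-calibrated"),
    p("u_gap_partial", "utility", 0.12, 0.06, 0.18,
      dist = dist_spec("beta", se = 0.015), units = "EQ-5D decrement",
      provenance = "synthetic; complete-to-partial utility difference"),
    p("u_gap_nonresponse", "utility", 0.16, 0.08, 0.20,
      dist = dist_spec("beta", se = 0.015), units = "EQ-5D decrement",
      provenance = "synthetic; partial-to-nonresponse utility difference"),
    p("u_pretreatment", "utility", 0.65, 0.55, 0.75,
      dist = dist_spec("beta", se = 0.02), units = "EQ-5D",
      provenance = "synthetic; active disease before response assessment"),
    p("u_no_treatment", "utility", 0.68, 0.58, 0.78,
      dist = dist_spec("beta", se = 0.02), units = "EQ-5D",
      provenance = "synthetic; off biologic therapy"),
    p("u_trend", "utility", 1.0, 1.0, 1.0,
      time_profile = rbind(c(0, 1.00), c(2, 1.02), c(5, 1.04), c(10, 1.05)),
      units = "multiplier",
      provenance = "synthetic; incident-cohort EQ-5D time trend, piecewise constant"),
    # --- glucocorticoid burden ---
    p("steroid_decrement", "utility", 0.005, 0.005, 0.005,
      units = "EQ-5D per mg/day prednisone equivalent",
      provenance = "printed: -0.005 EQ-5D per 1 mg/day prednisone equivalent",
      label = "printed"),
    p("pred_dose_pretreatment", "continuous", 20, 14, 26,
      dist = dist_spec("normal", se = 3), units = "mg/day",
      provenance = "synthetic; prednisone dose before response (delayed-arm baseline)"),
    p("pred_dose_complete", "continuous", 2.5, 1.75, 3.25,
      dist = dist_spec("normal", se = 0.4), units = "mg/day",
      provenance = "synthetic; tapered dose among complete responders"),
    p("pred_dose_partial", "continuous", 7.5, 5.25, 9.75,
      dist = dist_spec("normal", se = 1.1), units = "mg/day",
      provenance = "synthetic; dose among partial responders"),
    p("pred_dose_nonresponse", "continuous", 18, 12.6, 23.4,
      dist = dist_spec("normal", se = 2.2), units = "mg/day",
      provenance = "synthetic; dose among nonresponders"),
    p("pred_dose_no_treatment", "continuous", 10, 7, 13,
      dist = dist_spec("normal", se = 1.5), units = "mg/day",
      provenance = "synthetic; dose off biologic therapy"),
    p("pred_dose_reference", "continuous", 0, 0, 0,
      units = "mg/day",
      provenance = "assumption: decrement applied to absolute dose (reference 0 mg/day)"),
    p("pred_offset_early", "continuous", 10, 10, 10,
      units = "mg/day",
      provenance = "printed: early initiators on 10 mg/day more prednisone at baseline",
      label = "printed"),
    # --- costs (2024 USD) ---
    p("wac_belimumab_vial", "cost", 2450, dist = dist_spec("lognormal", se = 245),
      units = "USD per 400 mg vial",
      provenance = "synthetic; January 2025 WAC, belimumab 400 mg/5 mL"),
    p("wac_anifrolumab_vial", "cost", 1550, dist = dist_spec("lognormal", se = 155),
      units = "USD per 300 mg vial",
      provenance = "synthetic; January 2025 WAC, anifrolumab 300 mg/2 mL"),
    p("patient_weight_kg", "continuous", 70, 55, 85,
      dist = dist_spec("normal", se = 7), units = "kg",
      provenance = "assumption: mean body weight for 10 mg/kg dosing"),
    p("biologic_cost_scalar", "cost", 1.30477525692652, 0.25, 4.0,
      units = "multiplier on biologic acquisition cost",
      provenance = "synthetic-calibrated; absorbs administration and schedule costs not itemized",
      label = "synthetic-calibrated"),
    p("cost_pre", "cost", 9000, dist = dist_spec("lognormal", se = 2700),
      units = "USD/month",
      provenance = "synthetic; secondary direct costs before response (claims analysis)"),
    p("cost_cr", "cost", 5200, dist = dist_spec("lognormal", se = 1560),
      units = "USD/month",
      provenance = "synthetic; secondary direct costs, complete response"),
    p("cost_pr", "cost", 7000, dist = dist_spec("lognormal", se = 2100),
      units = "USD/month",
      provenance = "synthetic; secondary direct costs, partial response"),
    p("cost_nr", "cost", 33712.1272140178, 3000, 40000,
      dist = dist_spec("lognormal", se = 3300), units = "USD/month",
      provenance = "synthetic-calibrated; secondary direct costs, nonresponse (highest)",
      label = "synthetic-calibrated"),
    p("cost_off", "cost", 6500, dist = dist_spec("lognormal", se = 1950),
      units = "USD/month",
      provenance = "synthetic; secondary direct costs off treatment"),
    p("cost_trend", "cost", 1.0, 1.0, 1.0,
      time_profile = rbind(c(0, 1.00), c(1, 0.95), c(5, 0.90)),
      units = "multiplier",
      provenance = "synthetic; longitudinal decline of secondary costs after initiation"),
    # --- economics & scenarios ---
    p("wtp", "cost", 50000, 50000, 50000, units = "USD/QALY",
      provenance = "printed: willingness-to-pay threshold $50,000/QALY",
      label = "printed"),
    p("discount_rate", "probability", 0.03, 0.00, 0.05,
      units = "annual rate",
      provenance = "printed: 3% annual discounting; one-way range 0-5%",
      label = "printed"),
    p("biosim_discount_small", "probability", 0.15, 0.15, 0.15,
      units = "fraction of WAC",
      provenance = "printed: biosimilar substitution discount 15%",
      label = "printed"),
    p("biosim_discount_large", "probability", 0.60, 0.60, 0.60,
      units = "fraction of WAC",
      provenance = "printed: biosimilar substitution discount 60%",
      label = "printed"),
    p("biosim_erosion_multiplier", "probability", 0.75, 0.50, 1.00,
      units = "multiplier on WAC after biosimilar entry",
      provenance = "synthetic placeholder; post-biosimilar price-erosion estimate"))
  ledger(specs)
}

#' Default calibration targets: the published base-case totals
#'
#' @param tolerance Relative tolerance per target.
#' @return Data frame with `quantity`, `target`, `tolerance`.
#' @export
default_calibration_targets <- function(tolerance = 0.005) {
  stopifnot(tolerance > 0)
  data.frame(
    quantity = c("early_cost", "early_qaly", "delayed_cost", "delayed_qaly"),
    target = c(1910438.61, 7.68, 2036775.73, 7.38),
    tolerance = tolerance, stringsAsFactors = FALSE)
}

#' Default free parameters for calibration
#'
#' Four knobs for four targets, each dominantly influencing one target:
#' the SRI-4 response odds ratio (QALY gap; its base value is not printed,
#' only its one-way range, so it is calibrated within that range), the
#' complete-response utility anchor (QALY level), the nonresponse
#' secondary cost (delayed-arm cost), and the belimumab cost scalar
#' (early-arm cost).
#'
#' @return Character vector of ledger parameter names.
#' @export
default_free_parameters <- function() {
  c("or_sri4_early", "u_complete", "cost_nr", "biologic_cost_scalar")
}

# The four calibration quantities for a ledger at its current base values.
calibration_quantities <- function(ledg, settings, life_table,
                                   strategies = NULL) {
  cmp <- deterministic_comparison(ledg, settings, life_table, strategies)
  c(early_cost = cmp$cost_early, early_qaly = cmp$qaly_early,
    delayed_cost = cmp$cost_delayed, delayed_qaly = cmp$qaly_delayed)
}

#' Calibrate free parameters to the published base-case totals
#'
#' Bounded minimization (`stats::optim`, L-BFGS-B, deterministic start at
#' the ledger's current base values) of the sum of squared *relative*
#' residuals over the targets, so costs (~1e6 USD) and QALYs (~1e0) weigh
#' equally. The best point is returned even when not converged (flagged).
#'
#' @param ledg A `cea_ledger`.
#' @param free Names of free parameters (each must carry bounds).
#' @param targets Data frame as from [default_calibration_targets()].
#' @param settings A `cea_settings` list.
#' @param life_table Life-table data frame.
#' @return A `cea_calibration`: calibrated ledger and parameter values,
#'   per-target residuals, `converged`, iteration count.
#' @export
calibrate_to_base_case <- function(ledg,
                                   free = default_free_parameters(),
                                   targets = default_calibration_targets(),
                                   settings = analysis_settings(),
                                   life_table = generate_life_table()) {
  stopifnot(all(free %in% names(ledg$specs)))
  lo <- vapply(free, function(nm) ledg$specs[[nm]]$low, numeric(1))
  hi <- vapply(free, function(nm) ledg$specs[[nm]]$high, numeric(1))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi)) {
    stop("every free parameter needs finite non-degenerate bounds",
         call. = FALSE)
  }
  x0 <- base_values(ledg)[free]
  tv <- stats::setNames(targets$target, targets$quantity)

  residuals_at <- function(x) {
    l2 <- set_base_values(ledg, stats::setNames(x, free), relabel = FALSE)
    q <- calibration_quantities(l2, settings, life_table)
    q[targets$quantity] / tv - 1
  }
  n_eval <- 0L
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    sum(residuals_at(x)^2)
  }

  f0 <- objective(x0)
  tol2 <- sum((targets$tolerance / 2)^2)  # comfortably inside tolerance
  if (f0 <= tol2) {
    fit <- list(par = x0, value = f0, counts = c(0L, 0L))
  } else {
    fit <- stats::optim(x0, objective, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(parscale = pmax(abs(x0), 1e-3),
                                       factr = 1e4, maxit = 200))
  }
  res <- residuals_at(fit$par)
  converged <- all(abs(res) <= targets$tolerance)
  calibrated <- set_base_values(ledg, stats::setNames(fit$par, free))
  structure(list(ledger = calibrated,
                 par = stats::setNames(fit$par, free),
                 residuals = stats::setNames(res, targets$quantity),
                 converged = converged,
                 iterations = n_eval,
                 objective = fit$value,
                 targets = targets,
                 free = free), class = "cea_calibration")
}

#' @export
print.cea_calibration <- function(x, ...) {
  cat("<cea_calibration>", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "objective evaluations\n")
  for (nm in names(x$par)) {
    cat(sprintf("  %-18s = %.6g\n", nm, x$par[[nm]]))
  }
  for (nm in names(x$residuals)) {
    cat(sprintf("  residual %-13s = %+.3e\n", nm, x$residuals[[nm]]))
  }
  invisible(x)
}
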