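test_that("discount factors follow the annual compounding convention", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0, 500), 1)
  expect_equal(discount_factor(0.03, 12), 1 / 1.03, tolerance = 1e-15)
  expect_equal(discount_factor(0.03, 18), 1.03^-1.5, tolerance = 1e-15)
})

test_that("drug costing applies vial ceilings, loading doses, and contexts", {
  cm <- cost_model(base_case_parameters(default_ledger_f()))
  s <- cm$biologic_cost_scalar
  # 80 kg -> 800 mg -> 2 vials of 400 mg
  steady <- drug_cost_per_cycle(cm, "belimumab", 6, patient_weight_kg = 80)
  expect_equal(steady, 2 * cm$wac_belimumab_vial * s * 13 / 12)
  # 81 kg -> 810 mg -> 3 vials (wastage)
  expect_equal(drug_cost_per_cycle(cm, "belimumab", 6, patient_weight_kg = 81),
               3 * cm$wac_belimumab_vial * s * 13 / 12)
  # loading month carries two infusions
  expect_gt(drug_cost_per_cycle(cm, "belimumab", 1, patient_weight_kg = 80),
            steady)
  # anifrolumab: one fixed-dose vial
  expect_equal(drug_cost_per_cycle(cm, "anifrolumab", 6),
               cm$wac_anifrolumab_vial * s * 13 / 12)
  expect_identical(drug_cost_per_cycle(cm, "off_treatment", 6), 0)
  expect_error(drug_cost_per_cycle(cm, "chemo", 6), "unknown")
})

test_that("state utilities respect ordering and the glucocorticoid decrement", {
  params <- base_case_parameters(default_ledger_f())
  um <- utility_model(params)
  steroid <- steroid_trajectory(params)
  strat <- strategy_config("delayed")
  u <- vapply(c("complete_bel", "partial_bel", "nonresponse_bel"),
              function(s) state_utility_at(um, steroid, s, strat, 12),
              numeric(1))
  expect_true(all(diff(u) < 0))  # complete > partial > nonresponse

  # a 10 mg/day dose difference moves utility by exactly 0.05 pre-clamping
  p2 <- params
  p2$values[["pred_dose_complete"]] <- params$values[["pred_dose_complete"]] + 10
  u2 <- state_utility_at(utility_model(p2), steroid_trajectory(p2),
                         "complete_bel", strat, 12)
  expect_equal(u[["complete_bel"]] - u2, 0.05, tolerance = 1e-12)

  # the early arm's pretreatment offset only affects pretreatment
  early <- strategy_config("early")
  expect_equal(
    state_utility_at(um, steroid, "pretreatment_bel", strat, 0) -
      state_utility_at(um, steroid, "pretreatment_bel", early, 0),
    um$steroid_decrement_per_mg * steroid$early_offset, tolerance = 1e-12)
  expect_equal(state_utility_at(um, steroid, "complete_bel", strat, 0),
               state_utility_at(um, steroid, "complete_bel", early, 0))

  # utilities never leave the EQ-5D range
  p3 <- params
  p3$values[["pred_dose_nonresponse"]] <- 1000
  u3 <- state_utility_at(utility_model(p3), steroid_trajectory(p3),
                         "nonresponse_bel", strat, 0)
  expect_gte(u3, -0.594)
})

test_that("steroid decrement is linear in dose before clamping", {
  params <- base_case_parameters(default_ledger_f())
  strat <- strategy_config("delayed")
  doses <- c(0, 5, 12.5, 30)
  u <- vapply(doses, function(d) {
    p <- params
    p$values[["pred_dose_partial"]] <- d
    state_utility_at(utility_model(p), steroid_trajectory(p),
                     "partial_bel", strat, 24)
  }, numeric(1))
  expect_equal(diff(u), -0.005 * diff(doses), tolerance = 1e-12)
})

test_that("accumulation recovers the closed form for a constant cohort", {
  # flat utility u, zero mortality, zero discounting -> QALYs = u * years
  ledg <- default_ledger_f()
  ledg$specs$u_trend$time_profile <- NULL
  ledg$specs$cost_trend$time_profile <- NULL
  v <- base_values(ledg)
  v[c("u_complete", "u_pretreatment", "u_no_treatment")] <- 0.7
  v[c("u_gap_partial", "u_gap_nonresponse")] <- 0
  v[grep("^pred_dose", names(v))] <- 0
  v["pred_offset_early"] <- 0
  v["discount_rate"] <- 0
  params <- parameter_set(v, ledg)
  st <- effective_settings(params, analysis_settings(horizon_years = 5L))
  strat <- strategy_config("delayed")
  tr <- run_cohort(strat, params, st, immortal_life_table())
  res <- accumulate(tr, utility_model(params), cost_model(params),
                    steroid_trajectory(params), strat, st)
  expect_equal(res$qaly, 0.7 * 5, tolerance = 1e-9)
  expect_equal(res$qaly, res$qaly_undiscounted)
})

test_that("an all-dead cohort accrues nothing", {
  ledg <- default_ledger_f()
  params <- base_case_parameters(ledg)
  st <- short_settings(1L)
  tr <- run_cohort(strategy_config("early"), params, st, life_table_f())
  tr[, ] <- 0
  tr[, "death"] <- 1
  res <- accumulate(tr, utility_model(params), cost_model(params),
                    steroid_trajectory(params), strategy_config("early"), st)
  expect_equal(res$cost, 0)
  expect_equal(res$qaly, 0)
})

test_that("discounting can only shrink totals and audits reproduce them", {
  ledg <- calibrated_ledger_f()
  res <- run_strategy(strategy_config("early"),
                      base_case_parameters(ledg), analysis_settings(),
                      life_table_f())
  expect_lt(res$cost, res$cost_undiscounted)
  expect_lt(res$qaly, res$qaly_undiscounted)
  expect_equal(sum(res$audit$cost_discounted), res$cost, tolerance = 1e-9)
  expect_equal(sum(res$audit$qaly_discounted), res$qaly, tolerance = 1e-9)
  expect_equal(sum(res$audit$cost), res$cost_undiscounted,
               tolerance = 1e-9)
  # QALY upper bound: horizon x maximum utility
  expect_lte(res$qaly_undiscounted, 15 * 1)
})

test_that("raising a state utility or cost raises the respective total", {
  ledg <- calibrated_ledger_f()
  st <- analysis_settings()
  lt <- life_table_f()
  strat <- strategy_config("delayed")
  base <- run_strategy(strat, base_case_parameters(ledg), st, lt)
  up_u <- set_base_values(ledg, c(u_no_treatment =
    ledg$specs$u_no_treatment$base_value + 0.05), relabel = FALSE)
  up_c <- set_base_values(ledg, c(cost_pr =
    ledg$specs$cost_pr$base_value + 500), relabel = FALSE)
  expect_gt(run_strategy(strat, base_case_parameters(up_u), st, lt)$qaly,
            base$qaly)
  expect_gt(run_strategy(strat, base_case_parameters(up_c), st, lt)$cost,
            base$cost)
})

test_that("the vectorised accumulator agrees with the scalar valuation ops", {
  ledg <- calibrated_ledger_f()
  params <- base_case_parameters(ledg)
  st <- short_settings(2L)
  strat <- strategy_config("early")
  tr <- run_cohort(strat, params, st, life_table_f())
  um <- utility_model(params); cm <- cost_model(params)
  sx <- steroid_trajectory(params)
  res <- accumulate(tr, um, cm, sx, strat, st)
  liv <- internal_states[1:8]
  for (k in c(1L, 5L, 24L)) {
    u_k <- vapply(liv, function(s)
      state_utility_at(um, sx, s, strat, k - 1L), numeric(1))
    d_k <- vapply(liv, function(s)
      drug_cost_per_cycle(cm, lupuscea:::state_drug_context[[s]], k),
      numeric(1))
    sec_k <- cm$secondary[liv] * cm$cost_trend((k - 1) / 12)
    expect_equal(res$audit$qaly[k], sum(tr[k, liv] * u_k) / 12,
                 tolerance = 1e-12)
    expect_equal(res$audit$cost[k], sum(tr[k, liv] * (d_k + sec_k)),
                 tolerance = 1e-12)
  }
})

test_that("half-cycle correction averages adjacent occupancy rows", {
  ledg <- calibrated_ledger_f()
  params <- base_case_parameters(ledg)
  st0 <- short_settings(2L)
  st1 <- short_settings(2L, half_cycle_correction = TRUE)
  strat <- strategy_config("early")
  lt <- life_table_f()
  r0 <- run_strategy(strat, params, st0, lt)
  r1 <- run_strategy(strat, params, st1, lt)
  expect_false(isTRUE(all.equal(r0$qaly, r1$qaly)))
  # oracle: valuing the averaged trace without the correction flag must
  # reproduce the corrected run
  tr <- run_cohort(strat, params, st1, lt)
  n <- nrow(tr) - 1L
  tr_avg <- unclass(tr)
  tr_avg[1:n, ] <- (tr_avg[1:n, ] + tr_avg[2:(n + 1L), ]) / 2
  tr_avg <- structure(tr_avg, class = class(tr),
                      strategy = attr(tr, "strategy"))
  ref <- accumulate(tr_avg, utility_model(params), cost_model(params),
                    steroid_trajectory(params), strat, st0)
  expect_equal(r1$qaly, ref$qaly, tolerance = 1e-12)
  expect_equal(r1$cost, ref$cost, tolerance = 1e-12)
})
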