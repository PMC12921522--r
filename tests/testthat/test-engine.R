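test_that("annual-to-cycle conversion is exact and composes back", {
  expect_equal(annual_to_cycle_prob(0, 12), 0)
  expect_equal(annual_to_cycle_prob(1, 12), 1)
  m <- annual_to_cycle_prob(0.12, 12)
  expect_equal(m, 1 - 0.88^(1 / 12), tolerance = 1e-15)
  expect_equal(1 - (1 - m)^12, 0.12, tolerance = 1e-12)
  expect_error(annual_to_cycle_prob(1.5, 12), "outside")
})

test_that("odds-ratio transform is correct, monotone, and identity at 1", {
  p <- c(0.01, 0.3, 0.5, 0.99)
  expect_equal(apply_odds_ratio(p, 1), p)
  expect_equal(apply_odds_ratio(0.5, 3.47), 3.47 / 4.47, tolerance = 1e-15)
  expect_equal(apply_odds_ratio(c(0, 1), 2.5), c(0, 1))
  out <- vapply(c(1.1, 1.5, 2, 3), function(or) apply_odds_ratio(0.3, or),
                numeric(1))
  expect_true(all(diff(out) > 0))
  expect_error(apply_odds_ratio(0.5, -1), "positive")
})

test_that("mortality layer reproduces the life table at SMR 1 and scales hazards", {
  lt <- life_table_f()
  params <- base_case_parameters(default_ledger_f())
  unit_smr <- smr_table(parameter_set(
    replace(params$values, grep("^smr", names(params$values)), 1),
    default_ledger_f()))
  expect_true(all(unit_smr$smr == 1))

  # female-only cohort, SMR 1: monthly prob compounds to the table's qx
  q40 <- lt$qx[lt$sex == "female" & lt$age == 40]
  m <- cycle_death_prob(lt, unit_smr, 40, 1, 0)
  expect_equal(1 - (1 - m)^12, q40, tolerance = 1e-9)

  # SMR 2 doubles the hazard
  smr2 <- unit_smr; smr2$smr <- 2
  m2 <- cycle_death_prob(lt, smr2, 40, 1, 0)
  expect_equal(log(1 - m2), 2 * log(1 - m), tolerance = 1e-12)

  # age beyond table coverage errors
  expect_error(cycle_death_prob(lt, unit_smr, 101, 1, 0), "cover")
})

test_that("vectorised death path agrees with the per-cycle definition", {
  lt <- life_table_f()
  params <- base_case_parameters(default_ledger_f())
  smr <- smr_table(params)
  path <- lupuscea:::death_prob_path(lt, smr, 41, 0.912, 60)
  ref <- vapply(0:59, function(cy) cycle_death_prob(lt, smr, 41, 0.912, cy),
                numeric(1))
  expect_equal(path, ref, tolerance = 1e-15)
})

test_that("transition matrices are row-stochastic across random draws", {
  ledg <- default_ledger_f()
  strategies <- strategy_pair()
  set.seed(99)
  for (i in 1:20) {
    params <- draw_parameter_set(ledg)
    for (strat in strategies) {
      for (cy in c(0, 4, 5, 60)) {
        M <- build_transition_matrix(params, strat, cy, p_death = 0.002)
        expect_true(all(M >= 0 & M <= 1))
        expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
      }
    }
  }
  # death row is identity
  M <- build_transition_matrix(base_case_parameters(ledg),
                               strategies$early, 10, 0.01)
  expect_equal(unname(M["death", ]), c(rep(0, 8), 1))
})

test_that("degenerate transition inputs give an identity matrix", {
  ledg <- default_ledger_f()
  v <- base_values(ledg)
  v[c("p_cr_to_pr", "p_pr_to_cr", "p_pr_to_nr", "p_nr_to_pr", "p_nr_restart",
      "p_nr_stop", "p_nr_switch", "p_off_flare", "p_nr_ani_stop")] <- 0
  params <- parameter_set(v, ledg)
  M <- build_transition_matrix(params, strategy_config("early"),
                               cycle = 0, p_death = 0)  # induction phase
  expect_equal(unname(M), diag(9))
})

test_that("transition rows that sum above one are rejected by name", {
  ledg <- default_ledger_f()
  v <- base_values(ledg)
  v[c("p_pr_to_cr", "p_pr_to_nr")] <- c(0.7, 0.6)
  params <- parameter_set(v, ledg)
  expect_error(
    build_transition_matrix(params, strategy_config("early"), 10, 0),
    "partial_bel")
})

test_that("early and delayed matrices differ only in response-split rows", {
  params <- base_case_parameters(default_ledger_f())
  sp <- strategy_pair()
  Me <- build_transition_matrix(params, sp$early, 4, 0.001)
  Md <- build_transition_matrix(params, sp$delayed, 4, 0.001)
  diff_rows <- which(rowSums(abs(Me - Md)) > 0)
  expect_identical(names(diff_rows), "pretreatment_bel")
})

test_that("cohort trace conserves mass, starts in pretreatment, and absorbs death", {
  ledg <- calibrated_ledger_f()
  st <- analysis_settings()
  lt <- life_table_f()
  for (strat in strategy_pair()) {
    tr <- run_cohort(strat, base_case_parameters(ledg), st, lt)
    expect_equal(nrow(tr), 181L)
    expect_equal(unname(tr[1L, "pretreatment_bel"]), 1)
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-9)
    expect_true(all(tr >= -1e-15))
    expect_true(all(diff(tr[, "death"]) >= -1e-15))
  }
})

test_that("trace equals explicit matrix-product iteration", {
  ledg <- default_ledger_f()
  params <- base_case_parameters(ledg)
  st <- short_settings(3L)
  lt <- life_table_f()
  strat <- strategy_config("early")
  tr <- run_cohort(strat, params, st, lt)
  pd <- attr(tr, "p_death")
  mats <- lapply(seq_len(36) - 1L, function(cy)
    build_transition_matrix(params, strat, cy, pd[cy + 1L]))
  x0 <- c(1, rep(0, 8)); names(x0) <- internal_states
  ref <- iterate_cohort(x0, mats)
  expect_equal(unclass(tr), ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant-matrix iteration matches the closed-form matrix power", {
  M <- rbind(c(0.70, 0.20, 0.10),
             c(0.10, 0.80, 0.10),
             c(0.00, 0.00, 1.00))
  x0 <- c(1, 0, 0)
  tr <- iterate_cohort(x0, rep(list(M), 24))
  eig <- eigen(M)
  for (n in c(1, 6, 24)) {
    Mn <- Re(eig$vectors %*% diag(eig$values^n) %*% solve(eig$vectors))
    expect_equal(unname(tr[n + 1L, ]), drop(x0 %*% Mn), tolerance = 1e-12)
  }
})

test_that("with odds ratio 1 the two arms produce identical traces", {
  ledg <- no_effect_ledger()
  params <- base_case_parameters(ledg)
  st <- analysis_settings()
  lt <- life_table_f()
  sp <- strategy_pair()
  tr_e <- run_cohort(sp$early, params, st, lt)
  tr_d <- run_cohort(sp$delayed, params, st, lt)
  expect_identical(unclass(tr_e)[, ], unclass(tr_d)[, ])
})

test_that("SMR above 1 depresses survival relative to the general population", {
  ledg <- default_ledger_f()
  v1 <- base_values(ledg)
  v1[grep("^smr", names(v1))] <- 1
  st <- analysis_settings()
  lt <- life_table_f()
  strat <- strategy_config("early")
  tr_smr <- run_cohort(strat, base_case_parameters(ledg), st, lt)
  tr_gen <- run_cohort(strat, parameter_set(v1, ledg), st, lt)
  d <- tr_smr[-1L, "death"] - tr_gen[-1L, "death"]
  expect_true(all(d > 0))
})

test_that("the induction period holds the cohort in pretreatment", {
  ledg <- default_ledger_f()
  st <- analysis_settings()
  tr <- run_cohort(strategy_config("delayed"), base_case_parameters(ledg),
                   st, life_table_f())
  pre <- collapse_trace(tr)[, "pretreatment"]
  dead <- tr[, "death"]
  # rows 1..5 (cycles 0..4): everyone alive is still pretreatment
  expect_equal(pre[1:5] + dead[1:5], rep(1, 5), tolerance = 1e-12)
  # the split empties pretreatment at the induction boundary
  expect_lt(pre[6], 0.01)
})

test_that("total death forced from cycle one absorbs the cohort", {
  ledg <- default_ledger_f()
  lt <- immortal_life_table()
  lt$qx <- ifelse(lt$age >= 41, 1 - 1e-12, 0)  # certain death each year
  st <- short_settings(1L)
  tr <- run_cohort(strategy_config("early"), base_case_parameters(ledg),
                   st, lt)
  expect_gt(tr[3L, "death"], 0.9)
  expect_true(all(diff(tr[, "death"]) >= 0))
})
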