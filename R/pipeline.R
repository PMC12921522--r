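# Analysis settings, configuration handling, and the pipeline entry
# points tying all stages into one reproducible run.

#' Analysis settings
#'
#' Defaults mirror the modeled study design: 15-year horizon of monthly
#' cycles, 3% annual discounting, $50,000/QALY willingness-to-pay, 10,000
#' probabilistic simulations, 4-month induction, cohort starting age 41
#' with 91.2% female mix, no half-cycle correction.
#'
#' @param horizon_years Analytic horizon in years (>= 1).
#' @param cycles_per_year Cycles per year (12 = monthly).
#' @param discount_rate Annual discount rate.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param n_sims Probabilistic simulations.
#' @param seed Master seed.
#' @param half_cycle_correction Average adjacent occupancy rows when
#'   valuing cycles.
#' @param start_age Cohort age at model start (years).
#' @param female_fraction Fraction female.
#' @param induction_cycles Induction length in cycles.
#' @return A `cea_settings` list.
#' @export
analysis_settings <- function(horizon_years = 15L, cycles_per_year = 12L,
                              discount_rate = 0.03, wtp = 50000,
                              n_sims = 10000L, seed = 1L,
                              half_cycle_correction = FALSE,
                              start_age = 41, female_fraction = 0.912,
                              induction_cycles = 4L) {
  stopifnot(horizon_years >= 1, cycles_per_year >= 1, discount_rate >= 0,
            wtp >= 0, n_sims >= 1, female_fraction >= 0,
            female_fraction <= 1, induction_cycles >= 1)
  structure(list(horizon_years = as.integer(horizon_years),
                 cycles_per_year = as.integer(cycles_per_year),
                 discount_rate = discount_rate, wtp = wtp,
                 n_sims = as.integer(n_sims), seed = seed,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 start_age = start_age, female_fraction = female_fraction,
                 induction_cycles = as.integer(induction_cycles)),
            class = "cea_settings")
}

#' Settings with ledger overrides applied
#'
#' The discount rate and willingness-to-pay live in the ledger (so one-way
#' sensitivity analysis can vary them like any other parameter); when the
#' parameter set carries them they override the settings values.
#'
#' @param params A `cea_parameter_set`.
#' @param settings A `cea_settings` list.
#' @return The effective `cea_settings`.
#' @export
effective_settings <- function(params, settings) {
  if (!is.na(params$values["discount_rate"] %||% NA)) {
    settings$discount_rate <- unname(params$values[["discount_rate"]])
  }
  if (!is.na(params$values["wtp"] %||% NA)) {
    settings$wtp <- unname(params$values[["wtp"]])
  }
  settings
}

# Resolve a run configuration (YAML file or in-memory list) into
# ledger / life table / settings. Paths "default" and "synthetic" map to
# the shipped generators.
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  ledg <- config$ledger %||% "default"
  if (is.character(ledg)) {
    ledg <- if (identical(ledg, "default")) generate_default_ledger()
            else load_ledger(ledg)
  }
  lt <- config$life_table %||% "synthetic"
  if (is.character(lt)) {
    lt <- if (identical(lt, "synthetic")) generate_life_table()
          else load_life_table(lt)
  }
  st <- do.call(analysis_settings, config$settings %||% list())
  list(ledger = ledg, life_table = lt, settings = st,
       calibrate = isTRUE(config$calibrate %||% TRUE),
       ledger_path = if (is.character(config$ledger %||% "default"))
         config$ledger %||% "default" else "<in-memory>")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

run_manifest <- function(settings, ledger_hash, seed, outputs) {
  list(package_version = as.character(utils::packageVersion("lupuscea")),
       settings = unclass(settings), ledger_hash = ledger_hash,
       seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
       outputs = outputs)
}

ledger_hash <- function(ledg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_ledger(ledg, tmp)
  unname(tools::md5sum(tmp))
}

comparison_as_list <- function(cmp) {
  list(cost_early = cmp$cost_early, qaly_early = cmp$qaly_early,
       cost_delayed = cmp$cost_delayed, qaly_delayed = cmp$qaly_delayed,
       delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
       icer = if (isTRUE(attr(cmp$icer, "defined"))) as.numeric(cmp$icer)
              else NULL,
       icer_defined = isTRUE(attr(cmp$icer, "defined")),
       inmb = cmp$inmb, dominance = cmp$dominance, wtp = cmp$wtp)
}

#' Run the deterministic base case
#'
#' Resolves the configuration (ledger, life table, settings), optionally
#' runs the shipped calibration, executes both strategies at base values,
#' and (when `out` is given) writes a JSON summary, per-cycle audit CSVs,
#' and a run manifest.
#'
#' @param config Path to a YAML config, or a list with optional keys
#'   `ledger` (path or `"default"`), `life_table` (path or `"synthetic"`),
#'   `settings` (overrides for [analysis_settings()]), `calibrate`.
#' @param out Optional output directory.
#' @return Invisibly, a list with the `cea_comparison`, both
#'   `cea_strategy_result`s, the (possibly calibrated) ledger, and the
#'   manifest.
#' @export
run_base_case <- function(config = list(), out = NULL) {
  cfg <- resolve_config(config)
  ledg <- cfg$ledger
  calib <- NULL
  if (cfg$calibrate) {
    # targets are 15-year totals, so calibration runs at that horizon
    # regardless of the horizon requested for the analysis itself
    cal_st <- cfg$settings
    cal_st$horizon_years <- 15L
    calib <- calibrate_to_base_case(ledg, settings = cal_st,
                                    life_table = cfg$life_table)
    if (!calib$converged) {
      warning("calibration did not converge; using best point found")
    }
    ledg <- calib$ledger
  }
  strategies <- strategy_pair(cfg$settings$induction_cycles)
  params <- base_case_parameters(ledg)
  st <- effective_settings(params, cfg$settings)
  res_e <- run_strategy(strategies$early, params, st, cfg$life_table)
  res_d <- run_strategy(strategies$delayed, params, st, cfg$life_table)
  cmp <- compare_strategies(res_e, res_d, st$wtp)

  manifest <- NULL
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- c("base_case.json", "audit_early.csv", "audit_delayed.csv",
               "ledger_calibrated.yaml", "manifest.json")
    write_json_file(comparison_as_list(cmp), file.path(out, files[1L]))
    utils::write.csv(res_e$audit, file.path(out, files[2L]),
                     row.names = FALSE)
    utils::write.csv(res_d$audit, file.path(out, files[3L]),
                     row.names = FALSE)
    write_ledger(ledg, file.path(out, files[4L]))
    manifest <- run_manifest(st, ledger_hash(ledg), st$seed, files)
    write_json_file(manifest, file.path(out, files[5L]))
  }
  invisible(list(comparison = cmp, early = res_e, delayed = res_d,
                 ledger = ledg, calibration = calib, settings = st,
                 life_table = cfg$life_table, manifest = manifest))
}

#' Run the full analysis pipeline
#'
#' Base case, probabilistic sensitivity analysis, tornado, horizon sweep,
#' and the default pricing scenarios, under one master seed. Outputs are
#' written to `out` with a manifest listing every file.
#'
#' @param config As in [run_base_case()].
#' @param out Output directory.
#' @param n_sims Probabilistic simulation count (default from settings).
#' @param seed Master seed (default from settings).
#' @param horizons Horizons for the sweep.
#' @return Invisibly, a list with all stage results.
#' @export
run_full <- function(config = list(), out = NULL, n_sims = NULL,
                     seed = NULL, horizons = 1:25) {
  base <- run_base_case(config, out = out)
  st <- base$settings
  if (is.null(n_sims)) n_sims <- st$n_sims
  if (is.null(seed)) seed <- st$seed
  ledg <- base$ledger
  lt <- base$life_table

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("stage %-10s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  psa <- stage("psa", run_psa(ledg, st, lt, n_sims = n_sims, seed = seed))
  torn <- stage("tornado", tornado_analysis(ledg, st, lt))
  hs <- stage("horizons", horizon_sweep(ledg, st, lt, years = horizons))
  scen <- stage("scenarios", lapply(default_scenarios(ledg), function(sp)
    biosimilar_scenario(ledg, sp, st, lt)))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(psa$draws, file.path(out, "psa_draws.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$ceac, file.path(out, "ceac.csv"),
                     row.names = FALSE)
    write_json_file(list(
      n_sims = psa$n_sims, seed = psa$seed,
      mean_delta_cost = psa$mean_delta_cost,
      mean_delta_qaly = psa$mean_delta_qaly, mean_inmb = psa$mean_inmb,
      ui_delta_cost = as.list(psa$ui_delta_cost),
      ui_delta_qaly = as.list(psa$ui_delta_qaly),
      ui_inmb = as.list(psa$ui_inmb),
      quadrant_proportions = as.list(psa$quadrant_proportions),
      p_favor_early = psa$p_favor_early, n_clipped = psa$n_clipped),
      file.path(out, "psa_summary.json"))
    utils::write.csv(torn, file.path(out, "tornado.csv"),
                     row.names = FALSE)
    utils::write.csv(hs, file.path(out, "horizons.csv"), row.names = FALSE)
    write_json_file(lapply(scen, comparison_as_list),
                    file.path(out, "scenarios.json"))
    files <- c("base_case.json", "audit_early.csv", "audit_delayed.csv",
               "ledger_calibrated.yaml", "psa_draws.csv", "ceac.csv",
               "psa_summary.json", "tornado.csv", "horizons.csv",
               "scenarios.json", "manifest.json")
    write_json_file(run_manifest(st, ledger_hash(ledg), seed, files),
                    file.path(out, "manifest.json"))
  }
  invisible(list(base = base, psa = psa, tornado = torn, horizons = hs,
                 scenarios = scen))
}
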