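# Markov cohort engine. The six reported health states cannot remember
# which biologic a patient is on after switching, so the internal state
# space is expanded to health state x drug context and collapsed back to
# the six reported states for output.

#' Internal sub-states of the cohort model
#'
#' Eight living sub-states (health state crossed with drug context where it
#' matters) plus absorbing death. `collapse_trace()` maps them onto the six
#' reported health states.
#'
#' @format Character vector of internal state names.
#' @export
internal_states <- c(
  "pretreatment_bel", "complete_bel", "partial_bel", "nonresponse_bel",
  "complete_ani", "partial_ani", "nonresponse_ani",
  "no_treatment", "death")

#' The six reported health states
#' @format Character vector.
#' @export
health_states <- c("pretreatment", "complete_response", "partial_response",
                   "nonresponse", "no_treatment", "death")

# internal -> reported mapping
state_collapse_map <- c(
  pretreatment_bel = "pretreatment",
  complete_bel = "complete_response", partial_bel = "partial_response",
  nonresponse_bel = "nonresponse",
  complete_ani = "complete_response", partial_ani = "partial_response",
  nonresponse_ani = "nonresponse",
  no_treatment = "no_treatment", death = "death")

# internal state -> drug context (drug cost attribution)
state_drug_context <- c(
  pretreatment_bel = "belimumab", complete_bel = "belimumab",
  partial_bel = "belimumab", nonresponse_bel = "belimumab",
  complete_ani = "anifrolumab", partial_ani = "anifrolumab",
  nonresponse_ani = "anifrolumab",
  no_treatment = "off_treatment", death = "off_treatment")

#' Strategy configuration
#'
#' The two compared strategies share one model structure and one parameter
#' set; they differ only through declared parameters: the early arm applies
#' the SRI-4 response odds ratio to the induction response split and
#' carries a higher baseline prednisone dose.
#'
#' @param label `"early"` or `"delayed"`.
#' @param induction_cycles Months spent in pretreatment before the response
#'   split (default 4).
#' @param response_or_applied Whether the SRI-4 odds ratio multiplies the
#'   complete-response odds (early arm).
#' @param pred_offset_applied Whether the strategy's baseline prednisone
#'   offset applies in the pretreatment state (early arm).
#' @return A `cea_strategy`.
#' @export
strategy_config <- function(label, induction_cycles = 4L,
                            response_or_applied = identical(label, "early"),
                            pred_offset_applied = identical(label, "early")) {
  stopifnot(is.character(label), length(label) == 1L, induction_cycles >= 1L)
  structure(list(label = label,
                 induction_cycles = as.integer(induction_cycles),
                 first_biologic = "belimumab",
                 switch_biologic = "anifrolumab",
                 response_or_applied = isTRUE(response_or_applied),
                 pred_offset_applied = isTRUE(pred_offset_applied)),
            class = "cea_strategy")
}

#' The default early/delayed strategy pair
#'
#' @param induction_cycles Induction length in monthly cycles.
#' @return Named list with `early` and `delayed` `cea_strategy` objects.
#' @export
strategy_pair <- function(induction_cycles = 4L) {
  list(early = strategy_config("early", induction_cycles),
       delayed = strategy_config("delayed", induction_cycles))
}

#' Convert an annual probability to a per-cycle probability
#'
#' Constant-hazard conversion: `1 - (1 - p)^(1 / cycles_per_year)`, so that
#' compounding over a full year recovers the annual probability.
#'
#' @param p_annual Annual probability in \[0, 1\].
#' @param cycles_per_year Cycles per year (>= 1).
#' @return Per-cycle probability.
#' @export
annual_to_cycle_prob <- function(p_annual, cycles_per_year) {
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("annual probability outside [0, 1]", call. = FALSE)
  }
  stopifnot(cycles_per_year >= 1)
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' Apply an odds ratio to a probability
#'
#' Returns `odds^-1(or * odds(p))` with `odds(p) = p / (1 - p)`. Boundary
#' probabilities 0 and 1 are returned unchanged.
#'
#' @param p_base Baseline probability.
#' @param or Positive odds ratio.
#' @return Transformed probability in (0, 1) for interior `p_base`.
#' @export
apply_odds_ratio <- function(p_base, or) {
  if (any(or <= 0)) stop("odds ratio must be positive", call. = FALSE)
  ifelse(p_base <= 0 | p_base >= 1 | or == 1, p_base, {
    o <- or * p_base / (1 - p_base)
    o / (1 + o)
  })
}

#' Load a life table from CSV
#'
#' Expects columns `age`, `sex` (`"female"`/`"male"`), `qx` (annual death
#' probability).
#'
#' @param path CSV file path.
#' @return A validated life-table data frame.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table(lt)
  lt
}

validate_life_table <- function(lt) {
  if (!all(c("age", "sex", "qx") %in% names(lt))) {
    stop("life table needs columns age, sex, qx", call. = FALSE)
  }
  if (any(lt$qx < 0 | lt$qx > 1)) {
    stop("life-table qx outside [0, 1]", call. = FALSE)
  }
  for (s in c("female", "male")) {
    ages <- sort(lt$age[lt$sex == s])
    if (!length(ages)) stop("life table missing sex '", s, "'", call. = FALSE)
    if (any(diff(ages) != 1L)) {
      stop("life-table ages for '", s, "' are not contiguous", call. = FALSE)
    }
  }
  invisible(lt)
}

#' Standardized-mortality-ratio lookup table from a parameter set
#'
#' Builds the age-band by sex SMR map the mortality layer uses. The band
#' values are ledger parameters, jointly scaled by the `smr_multiplier`
#' parameter (the quantity varied in probabilistic analysis).
#'
#' @param params A `cea_parameter_set`.
#' @return Data frame with columns `sex`, `age_min`, `age_max`, `smr`.
#' @export
smr_table <- function(params) {
  m <- pv(params, "smr_multiplier")
  data.frame(
    sex = rep(c("female", "male"), each = 3L),
    age_min = rep(c(0, 40, 60), 2L),
    age_max = rep(c(39, 59, 200), 2L),
    smr = m * c(pv(params, "smr_f_young"), pv(params, "smr_f_mid"),
                pv(params, "smr_f_old"), pv(params, "smr_m_young"),
                pv(params, "smr_m_mid"), pv(params, "smr_m_old")),
    stringsAsFactors = FALSE)
}

smr_at <- function(smr_df, age, sex) {
  hit <- smr_df$sex == sex & smr_df$age_min <= age & age <= smr_df$age_max
  if (!any(hit)) stop("no SMR band covers age ", age, " sex ", sex,
                      call. = FALSE)
  smr_df$smr[which(hit)[1L]]
}

#' Per-cycle death probability from a life table and SMR map
#'
#' Current age is `age0 + cycle / cycles_per_year`, floored to whole years
#' for the life-table lookup. Each sex's annual death probability is
#' converted to a hazard (`-log(1 - qx)`), multiplied by its SMR, blended
#' across sexes at the hazard scale using the cohort's female fraction, and
#' converted back to a per-cycle probability.
#'
#' @param life_table Life-table data frame (`age`, `sex`, `qx`).
#' @param smr_df SMR map as returned by [smr_table()].
#' @param age0 Age at model start (years).
#' @param sex_mix Fraction female.
#' @param cycle Cycle index (0-based).
#' @param cycles_per_year Cycles per year.
#' @return Per-cycle death probability.
#' @export
cycle_death_prob <- function(life_table, smr_df, age0, sex_mix, cycle,
                             cycles_per_year = 12L) {
  age <- floor(age0 + cycle / cycles_per_year)
  rate <- 0
  for (s in c("female", "male")) {
    w <- if (s == "female") sex_mix else 1 - sex_mix
    if (w == 0) next
    qx <- life_table$qx[life_table$sex == s & life_table$age == age]
    if (!length(qx)) {
      stop("life table does not cover age ", age, " for sex '", s,
           "'; extend the table or shorten the horizon", call. = FALSE)
    }
    rate <- rate + w * (-log(1 - min(qx[1L], 1 - 1e-12)) * smr_at(smr_df, age, s))
  }
  annual_to_cycle_prob(1 - exp(-rate), cycles_per_year)
}

# Vectorised death-probability path over all cycles of a run; agrees with
# cycle_death_prob at every cycle (asserted in tests).
death_prob_path <- function(life_table, smr_df, age0, sex_mix, cycles,
                            cycles_per_year = 12L) {
  ages <- floor(age0 + (seq_len(cycles) - 1L) / cycles_per_year)
  uage <- sort(unique(ages))
  rate_u <- numeric(length(uage))
  for (s in c("female", "male")) {
    w <- if (s == "female") sex_mix else 1 - sex_mix
    if (w == 0) next
    sub <- life_table[life_table$sex == s, ]
    idx <- match(uage, sub$age)
    if (anyNA(idx)) {
      stop("life table does not cover age ", uage[which(is.na(idx))[1L]],
           " for sex '", s, "'; extend the table or shorten the horizon",
           call. = FALSE)
    }
    smr_u <- vapply(uage, function(a) smr_at(smr_df, a, s), numeric(1))
    rate_u <- rate_u + w * (-log(1 - pmin(sub$qx[idx], 1 - 1e-12)) * smr_u)
  }
  annual_to_cycle_prob(1 - exp(-rate_u), cycles_per_year)[match(ages, uage)]
}

# Induction response split for one strategy. The delayed arm's split is the
# ledger baseline; the early arm applies the SRI-4 odds ratio to the
# complete-response probability and rescales the partial/non split of the
# remaining mass proportionally.
response_split <- function(params, strategy) {
  p_cr <- pv(params, "p_induction_cr")
  p_pr <- pv(params, "p_induction_pr")
  if (p_cr + p_pr > 1) {
    stop("induction response probabilities sum above 1 ",
         "(p_induction_cr + p_induction_pr = ", p_cr + p_pr, ")",
         call. = FALSE)
  }
  or <- if (strategy$response_or_applied) pv(params, "or_sri4_early") else 1
  if (or != 1) {
    p_cr_new <- apply_odds_ratio(p_cr, or)
    p_pr <- if (p_cr < 1) p_pr * (1 - p_cr_new) / (1 - p_cr) else 0
    p_cr <- p_cr_new
  }
  c(cr = p_cr, pr = p_pr, nr = 1 - p_cr - p_pr)
}

# Anifrolumab response split on switch/flare entry: TULIP-style response
# probabilities attenuated for biologic-experienced patients.
ani_split <- function(params) {
  att <- pv(params, "ani_attenuation")
  a_cr <- att * pv(params, "p_ani_cr")
  a_pr <- att * pv(params, "p_ani_pr")
  if (a_cr + a_pr > 1) {
    stop("attenuated anifrolumab response probabilities sum above 1",
         call. = FALSE)
  }
  c(cr = a_cr, pr = a_pr, nr = 1 - a_cr - a_pr)
}

# Disease-transition matrix over the 8 living sub-states (no mortality;
# death is applied first each cycle and the remaining mass rescaled).
# phase: "induction" (pretreatment holds), "split" (whole pretreatment mass
# splits at the induction boundary), "post" (re-entrants after restart
# split at rate 1/induction_cycles per cycle).
disease_matrix <- function(params, strategy, phase) {
  n <- 8L
  liv <- internal_states[1:8]
  D <- matrix(0, n, n, dimnames = list(liv, liv))
  row_fill <- function(state, targets) {
    out <- sum(targets)
    if (out > 1 + 1e-12) {
      stop("transition probabilities out of state '", state,
           "' sum above 1 (", signif(out, 6), ")", call. = FALSE)
    }
    D[state, names(targets)] <<- targets
    D[state, state] <<- D[state, state] + (1 - out)
  }

  rs <- response_split(params, strategy)
  pre_split <- c(complete_bel = unname(rs["cr"]),
                 partial_bel = unname(rs["pr"]),
                 nonresponse_bel = unname(rs["nr"]))
  if (phase == "induction") {
    D["pretreatment_bel", "pretreatment_bel"] <- 1
  } else if (phase == "split") {
    D["pretreatment_bel", names(pre_split)] <- pre_split
  } else {
    # geometric re-induction: mean time to split equals the induction length
    rate <- 1 / strategy$induction_cycles
    row_fill("pretreatment_bel", pre_split * rate)
  }

  asp <- ani_split(params)
  ani_entry <- c(complete_ani = unname(asp["cr"]),
                 partial_ani = unname(asp["pr"]),
                 nonresponse_ani = unname(asp["nr"]))

  row_fill("complete_bel", c(partial_bel = pv(params, "p_cr_to_pr")))
  row_fill("partial_bel", c(complete_bel = pv(params, "p_pr_to_cr"),
                            nonresponse_bel = pv(params, "p_pr_to_nr")))
  row_fill("nonresponse_bel",
           c(partial_bel = pv(params, "p_nr_to_pr"),
             pretreatment_bel = pv(params, "p_nr_restart"),
             no_treatment = pv(params, "p_nr_stop"),
             pv(params, "p_nr_switch") * ani_entry))
  row_fill("complete_ani", c(partial_ani = pv(params, "p_cr_to_pr")))
  row_fill("partial_ani", c(complete_ani = pv(params, "p_pr_to_cr"),
                            nonresponse_ani = pv(params, "p_pr_to_nr")))
  row_fill("nonresponse_ani",
           c(partial_ani = pv(params, "p_nr_to_pr"),
             no_treatment = pv(params, "p_nr_ani_stop")))
  row_fill("no_treatment", pv(params, "p_off_flare") * ani_entry)
  D
}

phase_of <- function(cycle, induction_cycles) {
  if (cycle < induction_cycles) "induction"
  else if (cycle == induction_cycles) "split"
  else "post"
}

#' Build the full per-cycle transition matrix
#'
#' Assembles the 9 x 9 matrix over internal sub-states for one cycle:
#' the per-cycle death probability is applied first from every living
#' state and the remaining mass follows the disease-transition structure
#' (competing-risk, death-first convention). The death row is identity.
#'
#' @param params A `cea_parameter_set`.
#' @param strategy A `cea_strategy`.
#' @param cycle Cycle index (0-based; the matrix advances the cohort from
#'   `cycle` to `cycle + 1`).
#' @param p_death Per-cycle death probability for this cycle.
#' @return Row-stochastic 9 x 9 matrix with dimnames [internal_states].
#' @export
build_transition_matrix <- function(params, strategy, cycle, p_death) {
  stopifnot(cycle >= 0, p_death >= 0, p_death <= 1)
  D <- disease_matrix(params, strategy,
                      phase_of(cycle, strategy$induction_cycles))
  n <- length(internal_states)
  M <- matrix(0, n, n, dimnames = list(internal_states, internal_states))
  M[1:8, 1:8] <- (1 - p_death) * D
  M[1:8, "death"] <- p_death
  M["death", "death"] <- 1
  M
}

#' Iterate a cohort trace through a list of transition matrices
#'
#' Reference iteration `x_{t+1} = x_t M_t`; used directly by tests as the
#' matrix-product oracle and by [run_cohort()] through an algebraically
#' identical optimised path.
#'
#' @param x0 Initial occupancy row vector.
#' @param matrices List of square transition matrices, one per cycle.
#' @return Matrix with `length(matrices) + 1` rows of occupancies.
#' @export
iterate_cohort <- function(x0, matrices) {
  n <- length(matrices)
  out <- matrix(NA_real_, n + 1L, length(x0))
  colnames(out) <- names(x0)
  out[1L, ] <- x0
  x <- matrix(x0, 1L)
  for (i in seq_len(n)) {
    x <- x %*% matrices[[i]]
    out[i + 1L, ] <- x
  }
  out
}

#' Run the cohort through the model for one strategy
#'
#' Starts 100% of the cohort in pretreatment (on the strategy's first
#' biologic) and advances it one monthly cycle at a time: death first at
#' the life-table/SMR rate, then disease transitions. Returns the full
#' occupancy trace over internal sub-states.
#'
#' @param strategy A `cea_strategy`.
#' @param params A `cea_parameter_set`.
#' @param settings An `cea_settings` list (see [analysis_settings()]).
#' @param life_table Life-table data frame.
#' @return A `cea_trace`: occupancy matrix (`cycles + 1` rows) with
#'   attributes `strategy` and `p_death`.
#' @export
run_cohort <- function(strategy, params, settings, life_table) {
  cycles <- settings$horizon_years * settings$cycles_per_year
  stopifnot(cycles >= 0)
  pd <- if (cycles > 0) {
    death_prob_path(life_table, smr_table(params), settings$start_age,
                    settings$female_fraction, cycles,
                    settings$cycles_per_year)
  } else numeric(0)
  occ <- matrix(0, cycles + 1L, 9L,
                dimnames = list(NULL, internal_states))
  occ[1L, "pretreatment_bel"] <- 1
  if (cycles > 0) {
    # distinct disease matrices per phase (transitions carry no time trend)
    phases <- vapply(seq_len(cycles) - 1L, phase_of, character(1),
                     strategy$induction_cycles)
    mats <- lapply(unique(phases), function(ph)
      disease_matrix(params, strategy, ph))
    names(mats) <- unique(phases)
    x_liv <- occ[1L, 1:8]
    x_dead <- 0
    for (cy in seq_len(cycles)) {
      y <- drop(x_liv %*% mats[[phases[cy]]])
      p <- pd[cy]
      x_dead <- x_dead + p * sum(x_liv)
      x_liv <- (1 - p) * y
      occ[cy + 1L, 1:8] <- x_liv
      occ[cy + 1L, 9L] <- x_dead
    }
  }
  structure(occ, class = c("cea_trace", "matrix"),
            strategy = strategy$label, p_death = pd)
}

#' Collapse an internal trace onto the six reported health states
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @return Occupancy matrix with the six reported state columns.
#' @export
collapse_trace <- function(trace) {
  out <- sapply(health_states, function(h)
    rowSums(trace[, state_collapse_map == h, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, 1L,
                                       dimnames = list(NULL, health_states))
  out
}
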