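# Shared fixtures, built in code. Expensive objects are cached per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_ledger_f <- function() fixture("ledger", generate_default_ledger)

life_table_f <- function() fixture("life_table", generate_life_table)

calibrated_ledger_f <- function() {
  fixture("calibrated", function() {
    cal <- calibrate_to_base_case(default_ledger_f())
    stopifnot(cal$converged)
    cal$ledger
  })
}

# life table with zero mortality (deterministic-survival scenarios)
immortal_life_table <- function() {
  expand <- expand.grid(age = 0:100, sex = c("female", "male"),
                        stringsAsFactors = FALSE)
  expand$qx <- 0
  expand
}

# ledger with every distribution degenerate at the base value
all_fixed_ledger <- function(ledg = default_ledger_f()) {
  for (nm in names(ledg$specs)) {
    ledg$specs[[nm]]$dist <- dist_spec("fixed")
  }
  ledg
}

# ledger with no early-arm effect: odds ratio 1 (held fixed so PSA draws
# cannot move it) and no baseline prednisone offset
no_effect_ledger <- function(ledg = default_ledger_f()) {
  ledg <- set_base_values(ledg, c(or_sri4_early = 1, pred_offset_early = 0),
                          relabel = FALSE)
  ledg$specs$or_sri4_early$dist <- dist_spec("fixed")
  ledg
}

short_settings <- function(years = 2L, ...) {
  analysis_settings(horizon_years = years, ...)
}
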