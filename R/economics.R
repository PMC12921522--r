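# Incremental cost-effectiveness quantities and decision summaries.

#' Incremental cost-effectiveness ratio
#'
#' `(early cost - delayed cost) / (early QALY - delayed QALY)`. A zero QALY
#' increment yields an undefined-flag result (`NA` with
#' `attr(, "defined") = FALSE`), never a division error. Negative ratios
#' are reported as-is; interpretation travels with the dominance label.
#'
#' @param cost_early,qaly_early Totals for the early strategy.
#' @param cost_delayed,qaly_delayed Totals for the delayed strategy.
#' @return USD per QALY, with attribute `defined`.
#' @export
icer <- function(cost_early, qaly_early, cost_delayed, qaly_delayed) {
  dq <- qaly_early - qaly_delayed
  if (dq == 0) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure((cost_early - cost_delayed) / dq, defined = TRUE)
}

#' Incremental net monetary benefit
#'
#' `delta_qaly * wtp - delta_cost`.
#'
#' @param delta_qaly Incremental QALYs (early minus delayed).
#' @param delta_cost Incremental cost (early minus delayed, USD).
#' @param wtp Willingness-to-pay threshold (USD/QALY, >= 0).
#' @return INMB in USD.
#' @export
inmb <- function(delta_qaly, delta_cost, wtp) {
  stopifnot(all(wtp >= 0))
  delta_qaly * wtp - delta_cost
}

#' Cost-effectiveness plane quadrant of an incremental pair
#'
#' `"NE"` (+cost, +QALY), `"SE"` (-cost, +QALY), `"SW"` (-cost, -QALY),
#' `"NW"` (+cost, -QALY). Boundary convention: zeros are assigned to the
#' positive-QALY side, and a zero on both axes is `"SE"`.
#'
#' @param delta_cost,delta_qaly Incremental cost and QALYs (vectorised).
#' @return Character vector of quadrant labels.
#' @export
classify_quadrant <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly >= 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost > 0, "NW", "SW"))
}

dominance_label <- function(delta_cost, delta_qaly) {
  if (delta_cost < 0 && delta_qaly > 0) "dominant"
  else if (delta_cost > 0 && delta_qaly < 0) "dominated"
  else if (delta_qaly >= 0) "tradeoff_ne"
  else "tradeoff_sw"
}

#' Compare two strategy results
#'
#' @param early,delayed `cea_strategy_result` objects.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return A `cea_comparison` with `delta_cost`, `delta_qaly`, `icer`,
#'   `inmb`, `dominance`, `wtp`, and the two input totals.
#' @export
compare_strategies <- function(early, delayed, wtp = 50000) {
  dc <- early$cost - delayed$cost
  dq <- early$qaly - delayed$qaly
  structure(list(
    cost_early = early$cost, qaly_early = early$qaly,
    cost_delayed = delayed$cost, qaly_delayed = delayed$qaly,
    delta_cost = dc, delta_qaly = dq,
    icer = icer(early$cost, early$qaly, delayed$cost, delayed$qaly),
    inmb = inmb(dq, dc, wtp),
    dominance = dominance_label(dc, dq),
    quadrant = classify_quadrant(dc, dq),
    wtp = wtp), class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("<cea_comparison> early vs delayed\n")
  cat(sprintf("  early:   $%.2f / %.4f QALYs\n", x$cost_early, x$qaly_early))
  cat(sprintf("  delayed: $%.2f / %.4f QALYs\n", x$cost_delayed,
              x$qaly_delayed))
  cat(sprintf("  delta:   $%.2f / %.4f QALYs\n", x$delta_cost, x$delta_qaly))
  ic <- if (isTRUE(attr(x$icer, "defined"))) sprintf("$%.2f/QALY", x$icer)
        else "undefined (zero QALY increment)"
  cat(sprintf("  ICER %s; INMB $%.2f at WTP $%.0f/QALY (%s)\n", ic, x$inmb,
              x$wtp, x$dominance))
  invisible(x)
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' At each willingness-to-pay value, the probability that early initiation
#' is optimal is the fraction of draws with positive incremental net
#' monetary benefit; draws with INMB exactly zero are split 0.5/0.5
#' between the strategies (measure-zero tie convention). The two
#' probabilities sum to 1 at every grid point.
#'
#' @param delta_cost,delta_qaly Paired incremental draws.
#' @param wtp_grid Non-empty numeric grid of WTP values.
#' @return Data frame with `wtp`, `p_early`, `p_delayed`.
#' @export
ceac_from_draws <- function(delta_cost, delta_qaly,
                            wtp_grid = seq(0, 150000, by = 5000)) {
  if (!length(delta_cost)) stop("no PSA draws supplied", call. = FALSE)
  stopifnot(length(delta_cost) == length(delta_qaly), length(wtp_grid) > 0)
  p_early <- vapply(wtp_grid, function(w) {
    b <- inmb(delta_qaly, delta_cost, w)
    mean((b > 0) + 0.5 * (b == 0))
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_early = p_early, p_delayed = 1 - p_early)
}
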