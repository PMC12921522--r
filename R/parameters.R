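# Parameter ledger: the single source of truth for every numeric input of
# the model. Each entry carries a base value, one-way sensitivity bounds,
# a sampling distribution for probabilistic analysis, and a provenance note.

#' Distribution specification for a ledger parameter
#'
#' Describes how a parameter is sampled in probabilistic sensitivity
#' analysis. Probabilities and utilities use beta distributions, costs and
#' odds ratios log-normal, continuous clinical parameters normal, and
#' structural constants are `fixed`.
#'
#' Moment-matched specs (`derivation = "moment-matched-from-mean-se"`) store
#' only a standard error; the shape parameters are re-derived from the
#' parameter's *current* base value at sampling time, so recalibrating a
#' base value automatically re-centres its distribution. Direct specs store
#' explicit shape parameters (`param_a`, `param_b`).
#'
#' @param family One of `"beta"`, `"lognormal"`, `"normal"`, `"fixed"`.
#' @param se Standard error on the natural scale (moment-matched specs).
#' @param param_a,param_b Explicit family parameters (direct specs):
#'   shape1/shape2 for beta, meanlog/sdlog for lognormal, mean/sd for normal.
#' @return A `cea_dist` list.
#' @export
dist_spec <- function(family = c("fixed", "beta", "lognormal", "normal"),
                      se = NULL, param_a = NULL, param_b = NULL) {
  family <- match.arg(family)
  if (family == "fixed") {
    out <- list(family = "fixed", derivation = "direct",
                param_a = NULL, param_b = NULL, se = NULL)
  } else if (!is.null(se)) {
    if (!is.numeric(se) || se < 0) {
      stop("'se' must be a non-negative number", call. = FALSE)
    }
    out <- list(family = family, derivation = "moment-matched-from-mean-se",
                param_a = NULL, param_b = NULL, se = se)
  } else {
    if (is.null(param_a) || is.null(param_b)) {
      stop("non-fixed direct specs need 'param_a' and 'param_b'",
           call. = FALSE)
    }
    out <- list(family = family, derivation = "direct",
                param_a = param_a, param_b = param_b, se = NULL)
  }
  structure(out, class = "cea_dist")
}

#' Fit a beta distribution by moment matching
#'
#' Given a mean in (0, 1) and a standard error, returns the beta spec whose
#' first two moments reproduce them: with `k = mean (1 - mean) / se^2 - 1`,
#' `shape1 = mean k` and `shape2 = (1 - mean) k`.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @return A direct `cea_dist` with family `"beta"`.
#' @export
fit_beta_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L,
            length(se) == 1L)
  if (mean <= 0 || mean >= 1) {
    stop("beta moment fit needs 0 < mean < 1, got ", mean, call. = FALSE)
  }
  if (se <= 0 || se^2 >= mean * (1 - mean)) {
    stop("infeasible se for beta moment fit (need se^2 < mean*(1-mean)); ",
         "widen or clip the ledger entry", call. = FALSE)
  }
  k <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", param_a = mean * k, param_b = (1 - mean) * k)
}

#' Fit a log-normal distribution by moment matching
#'
#' Given an arithmetic mean and standard error, returns the log-normal spec
#' with `sdlog^2 = log(1 + se^2 / mean^2)` and
#' `meanlog = log(mean) - sdlog^2 / 2`, so the arithmetic moments of the
#' spec equal the inputs.
#'
#' @param mean Positive arithmetic mean.
#' @param se Positive standard error.
#' @return A direct `cea_dist` with family `"lognormal"`.
#' @export
fit_lognormal_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L,
            length(se) == 1L)
  if (mean <= 0) stop("log-normal moment fit needs mean > 0", call. = FALSE)
  if (se < 0) stop("'se' must be non-negative", call. = FALSE)
  s2 <- log1p(se^2 / mean^2)
  dist_spec("lognormal", param_a = log(mean) - s2 / 2, param_b = sqrt(s2))
}

#' Analytic mean and sd of a distribution spec
#'
#' @param dist A `cea_dist`.
#' @param base_value Base value used to centre moment-matched and fixed
#'   specs.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(dist, base_value = NULL) {
  if (dist$derivation == "moment-matched-from-mean-se") {
    return(c(mean = base_value, sd = dist$se))
  }
  switch(dist$family,
    fixed = c(mean = base_value, sd = 0),
    beta = {
      a <- dist$param_a; b <- dist$param_b
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    lognormal = {
      m <- exp(dist$param_a + dist$param_b^2 / 2)
      c(mean = m, sd = m * sqrt(expm1(dist$param_b^2)))
    },
    normal = c(mean = dist$param_a, sd = dist$param_b)
  )
}

valid_roles <- c("probability", "utility", "cost", "odds_ratio", "continuous")

# Distribution family each role takes under the model's assignment rule.
role_families <- c(probability = "beta", utility = "beta", cost = "lognormal",
                   odds_ratio = "lognormal", continuous = "normal")

#' Define one ledger parameter
#'
#' @param name Unique identifier.
#' @param role One of `"probability"`, `"utility"`, `"cost"`,
#'   `"odds_ratio"`, `"continuous"`.
#' @param base_value Deterministic base-case value.
#' @param low,high One-way sensitivity bounds. When missing they default to
#'   base -/+ 30% on the parameter's natural scale (probabilities capped to
#'   \[0, 1\]).
#' @param dist A `cea_dist`; defaults to `fixed`.
#' @param units Free-text units.
#' @param time_profile Optional two-column matrix or list of `(year, value)`
#'   anchors for time-varying parameters; values are held piecewise constant
#'   between anchors.
#' @param provenance Free-text citation / derivation note.
#' @param label `"printed"` for values printed in the source analysis,
#'   `"synthetic"` or `"synthetic-calibrated"` otherwise.
#' @return A `cea_param` list.
#' @export
param_spec <- function(name, role, base_value, low = NULL, high = NULL,
                       dist = dist_spec("fixed"), units = "",
                       time_profile = NULL, provenance = "",
                       label = "synthetic") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, valid_roles)
  stopifnot(is.numeric(base_value), length(base_value) == 1L)
  defaulted <- is.null(low) || is.null(high)
  if (is.null(low)) low <- base_value - 0.30 * abs(base_value)
  if (is.null(high)) high <- base_value + 0.30 * abs(base_value)
  if (role == "probability") {
    low <- max(low, 0)
    high <- min(high, 1)
  }
  if (role == "cost") low <- max(low, 0)
  if (!is.null(time_profile)) {
    time_profile <- as.matrix(time_profile)
    if (ncol(time_profile) != 2L) {
      stop("time_profile for '", name, "' must have (year, value) columns",
           call. = FALSE)
    }
    colnames(time_profile) <- c("year", "value")
    time_profile <- time_profile[order(time_profile[, "year"]), ,
                                 drop = FALSE]
  }
  structure(
    list(name = name, role = role, base_value = base_value,
         low = low, high = high, dist = dist, units = units,
         time_profile = time_profile, provenance = provenance,
         label = label, range_defaulted = defaulted),
    class = "cea_param")
}

#' Assemble a parameter ledger
#'
#' @param ... `cea_param` entries, or a single list of them.
#' @param schema_version Schema version string.
#' @return A `cea_ledger`.
#' @export
ledger <- function(..., schema_version = "1") {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "cea_param")) {
    specs <- specs[[1L]]
  }
  ok <- vapply(specs, inherits, logical(1), "cea_param")
  if (!all(ok)) stop("all ledger entries must be cea_param objects",
                     call. = FALSE)
  nms <- vapply(specs, `[[`, character(1), "name")
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) {
    stop("duplicate parameter name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(specs) <- nms
  structure(list(specs = specs, schema_version = schema_version),
            class = "cea_ledger")
}

#' @export
print.cea_ledger <- function(x, ...) {
  cat("<cea_ledger> ", length(x$specs), " parameters (schema ",
      x$schema_version, ")\n", sep = "")
  roles <- table(vapply(x$specs, `[[`, character(1), "role"))
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
`[[.cea_ledger` <- function(x, i) x$specs[[i]]

#' Replace base values in a ledger
#'
#' Used by calibration and scenario machinery. Bounds are widened if the new
#' base falls outside `[low, high]`, and the entry is relabelled
#' `"synthetic-calibrated"` unless it was printed.
#'
#' @param ledg A `cea_ledger`.
#' @param values Named numeric vector of new base values.
#' @param relabel Whether to relabel touched synthetic entries.
#' @return The updated ledger.
#' @export
set_base_values <- function(ledg, values, relabel = TRUE) {
  stopifnot(inherits(ledg, "cea_ledger"))
  missing <- setdiff(names(values), names(ledg$specs))
  if (length(missing)) {
    stop("unknown parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(values)) {
    sp <- ledg$specs[[nm]]
    sp$base_value <- unname(values[[nm]])
    sp$low <- min(sp$low, sp$base_value)
    sp$high <- max(sp$high, sp$base_value)
    if (relabel && sp$label != "printed") sp$label <- "synthetic-calibrated"
    ledg$specs[[nm]] <- sp
  }
  ledg
}

#' Base-case values of a ledger
#'
#' @param ledg A `cea_ledger`.
#' @return Named numeric vector of base values.
#' @export
base_values <- function(ledg) {
  vapply(ledg$specs, `[[`, numeric(1), "base_value")
}

#' Validate a parameter ledger
#'
#' Checks that required parameters are present, ranges bracket base values,
#' role-specific supports hold, and each non-fixed distribution family
#' matches its role under the model's assignment rule (beta for
#' probabilities and utilities, log-normal for costs and odds ratios,
#' normal for continuous parameters).
#'
#' @param ledg A `cea_ledger`.
#' @param required Character vector of names the engine needs (default:
#'   [required_parameters()]).
#' @return A data frame report with columns `parameter`, `field`,
#'   `problem`; zero rows when the ledger is usable.
#' @export
validate_ledger <- function(ledg, required = required_parameters()) {
  stopifnot(inherits(ledg, "cea_ledger"))
  rows <- list()
  note <- function(parameter, field, problem) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, field = field, problem = problem,
      stringsAsFactors = FALSE)
  }
  for (nm in setdiff(required, names(ledg$specs))) {
    note(nm, "name", "required parameter missing")
  }
  for (sp in ledg$specs) {
    if (!(sp$low <= sp$base_value && sp$base_value <= sp$high)) {
      note(sp$name, "range", "low <= base_value <= high violated")
    }
    if (sp$role == "probability" &&
        (sp$base_value < 0 || sp$base_value > 1 || sp$low < 0 ||
         sp$high > 1)) {
      note(sp$name, "base_value", "probability outside [0, 1]")
    }
    if (sp$role == "utility" && (sp$base_value < -0.594 ||
                                 sp$base_value > 1)) {
      note(sp$name, "base_value", "utility outside EQ-5D range [-0.594, 1]")
    }
    if (sp$role == "cost" && sp$low < 0) {
      note(sp$name, "low", "cost bound negative")
    }
    if (sp$role == "odds_ratio" && sp$base_value <= 0) {
      note(sp$name, "base_value", "odds ratio must be positive")
    }
    fam <- sp$dist$family
    if (fam != "fixed" && fam != role_families[[sp$role]]) {
      note(sp$name, "distribution",
           paste0("family '", fam, "' inconsistent with role '", sp$role,
                  "' (expected '", role_families[[sp$role]], "')"))
    }
  }
  if (!length(rows)) {
    return(data.frame(parameter = character(), field = character(),
                      problem = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Draw one parameter set from a ledger
#'
#' Draws every parameter independently from its distribution using the
#' current RNG state (seed the stream with [set.seed()] before calling for
#' reproducibility). Fixed parameters return their base value. Normal draws
#' for probability-role parameters that land outside \[0, 1\] are clipped
#' and counted; beta and clipped events are reported in the result's
#' `n_clipped` field, never silently accepted.
#'
#' @param ledg A valid `cea_ledger`.
#' @param label Label stored on the result.
#' @param draw_index Optional draw index.
#' @return A `cea_parameter_set`: list with `values` (named numeric),
#'   `label`, `draw_index`, `n_clipped`.
#' @export
draw_parameter_set <- function(ledg, label = "psa_draw", draw_index = NULL) {
  stopifnot(inherits(ledg, "cea_ledger"))
  n_clipped <- 0L
  values <- vapply(ledg$specs, function(sp) {
    d <- sp$dist
    if (d$family == "fixed") return(sp$base_value)
    if (d$derivation == "moment-matched-from-mean-se") {
      d <- switch(d$family,
        beta = fit_beta_from_moments(sp$base_value, d$se),
        lognormal = fit_lognormal_from_moments(sp$base_value, d$se),
        normal = dist_spec("normal", param_a = sp$base_value,
                           param_b = d$se))
    }
    x <- switch(d$family,
      beta = stats::rbeta(1L, d$param_a, d$param_b),
      lognormal = stats::rlnorm(1L, d$param_a, d$param_b),
      normal = stats::rnorm(1L, d$param_a, d$param_b))
    if (sp$role %in% c("probability", "utility") && (x < 0 || x > 1)) {
      x <- min(max(x, 0), 1)
      n_clipped <<- n_clipped + 1L
    }
    x
  }, numeric(1))
  parameter_set(values, ledg, label = label, draw_index = draw_index,
                n_clipped = n_clipped)
}

#' Build a parameter set from explicit values
#'
#' @param values Named numeric vector covering the ledger's parameters.
#' @param ledg Ledger the values belong to (time profiles are carried over).
#' @param label,draw_index,n_clipped Metadata fields.
#' @return A `cea_parameter_set`.
#' @export
parameter_set <- function(values, ledg, label = "base_case",
                          draw_index = NULL, n_clipped = 0L) {
  profiles <- Filter(Negate(is.null),
                     lapply(ledg$specs, `[[`, "time_profile"))
  structure(list(values = values, label = label, draw_index = draw_index,
                 n_clipped = n_clipped, time_profiles = profiles),
            class = "cea_parameter_set")
}

#' Base-case parameter set of a ledger
#'
#' @param ledg A `cea_ledger`.
#' @return A `cea_parameter_set` holding every base value.
#' @export
base_case_parameters <- function(ledg) {
  parameter_set(base_values(ledg), ledg, label = "base_case")
}

# Look up a parameter value, with a hard error naming the parameter so
# engine/ledger drift is caught immediately.
pv <- function(params, name) {
  v <- params$values[[name]]
  if (is.null(v) || is.na(v)) {
    stop("parameter '", name, "' missing from parameter set", call. = FALSE)
  }
  v
}

# Value of a (possibly time-varying) parameter at a given model year.
# Time profiles are piecewise constant between anchors: the value is the
# anchor value scaled so that the year-0 anchor equals the drawn value.
pv_at <- function(params, name, year) {
  v <- pv(params, name)
  prof <- params$time_profiles[[name]]
  if (is.null(prof)) return(rep(v, length(year)))
  i <- findInterval(year, prof[, "year"])
  i[i < 1L] <- 1L
  unname(v * prof[i, "value"] / prof[1L, "value"])
}

#' Write a ledger to YAML
#'
#' @param ledg A `cea_ledger`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledg, path) {
  stopifnot(inherits(ledg, "cea_ledger"))
  entries <- lapply(ledg$specs, function(sp) {
    d <- sp$dist
    dist <- if (d$family == "fixed") {
      list(family = "fixed")
    } else if (d$derivation == "moment-matched-from-mean-se") {
      list(family = d$family, se = d$se)
    } else {
      list(family = d$family, a = d$param_a, b = d$param_b)
    }
    out <- list(name = sp$name, role = sp$role, base_value = sp$base_value,
                low = sp$low, high = sp$high, units = sp$units,
                distribution = dist, provenance = sp$provenance,
                label = sp$label)
    if (!is.null(sp$time_profile)) {
      out$time_profile <- lapply(seq_len(nrow(sp$time_profile)), function(i)
        as.numeric(sp$time_profile[i, ]))
    }
    out
  })
  yaml::write_yaml(list(schema_version = ledg$schema_version,
                        parameters = unname(entries)), path)
  invisible(path)
}

#' Load a ledger from YAML
#'
#' Reads the documented ledger schema: a `parameters` list of entries with
#' `name`, `role`, `base_value`, optional `low`/`high` (defaulted to +/-30%
#' when absent), `units`, `distribution` (`family` plus either `se` or
#' `a`/`b`), optional `time_profile` anchors, and `provenance`.
#'
#' @param path Path to a YAML ledger file.
#' @return A `cea_ledger` passing [validate_ledger()] structure checks.
#' @export
load_ledger <- function(path) {
  if (!file.exists(path)) {
    stop("ledger file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$parameters)) {
    stop("ledger file has no 'parameters' list: ", path, call. = FALSE)
  }
  specs <- lapply(raw$parameters, function(e) {
    for (field in c("name", "role", "base_value")) {
      if (is.null(e[[field]])) {
        stop("ledger entry ", if (!is.null(e$name)) paste0("'", e$name, "' "),
             "missing field '", field, "'", call. = FALSE)
      }
    }
    d <- e$distribution
    dist <- if (is.null(d) || identical(d$family, "fixed")) {
      dist_spec("fixed")
    } else if (!is.null(d$se)) {
      dist_spec(d$family, se = d$se)
    } else {
      dist_spec(d$family, param_a = d$a, param_b = d$b)
    }
    tp <- if (!is.null(e$time_profile)) {
      do.call(rbind, lapply(e$time_profile, as.numeric))
    }
    param_spec(e$name, e$role, e$base_value, low = e$low, high = e$high,
               dist = dist, units = e$units %||% "", time_profile = tp,
               provenance = e$provenance %||% "",
               label = e$label %||% "synthetic")
  })
  ledger(specs, schema_version = raw$schema_version %||% "1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
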