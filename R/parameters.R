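#' Probability, rate and currency conversions
#'
#' Small deterministic conversions used throughout the model: relative-risk
#' scaling of probabilities, constant-hazard rescaling of annual probabilities
#' to model cycles, incidence-rate to annual-probability conversion, and
#' PLN/EUR currency conversion.
#'
#' @name conversions
NULL

#' Scale a probability by a relative risk
#'
#' Multiplies a comparator-arm probability by a relative risk and caps the
#' result at 1. This is how every intervention-arm probability in the model is
#' derived from its standard-care counterpart.
#'
#' @param p Probability in `[0, 1]`.
#' @param rr Positive relative risk.
#' @return `min(p * rr, 1)`.
#' @export
#' @examples
#' apply_relative_risk(0.25, 1.34) # 0.335
apply_relative_risk <- function(p, rr) {
  stopifnot(is.numeric(p), is.numeric(rr))
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  if (any(rr <= 0)) stop("'rr' must be positive")
  pmin(p * rr, 1)
}

#' Convert an annual probability to a cycle probability
#'
#' Constant-hazard conversion: the event hazard is assumed uniform within the
#' year, so the probability over a fraction `f` of a year is
#' `1 - (1 - p_annual)^f`.
#'
#' @param p_annual Annual event probability in `[0, 1]`.
#' @param cycle_fraction_of_year Cycle length as a fraction of a year, in
#'   `(0, 1]` (an 8-week cycle is `8/52`).
#' @return Cycle probability.
#' @export
#' @examples
#' annual_prob_to_cycle(0.0475, 8 / 52) # ~0.0075
annual_prob_to_cycle <- function(p_annual, cycle_fraction_of_year) {
  stopifnot(is.numeric(p_annual), is.numeric(cycle_fraction_of_year))
  if (any(p_annual < 0 | p_annual > 1)) stop("'p_annual' must be in [0, 1]")
  if (any(cycle_fraction_of_year <= 0 | cycle_fraction_of_year > 1)) {
    stop("'cycle_fraction_of_year' must be in (0, 1]")
  }
  if (any(p_annual == 1)) {
    warning("p_annual = 1 has infinite hazard; returning 1 for those entries")
  }
  1 - (1 - p_annual)^cycle_fraction_of_year
}

#' Re-annualise a cycle probability
#'
#' Inverse of [annual_prob_to_cycle()] under the same constant-hazard
#' assumption.
#'
#' @inheritParams annual_prob_to_cycle
#' @param p_cycle Cycle event probability in `[0, 1]`.
#' @return Annual probability.
#' @export
cycle_prob_to_annual <- function(p_cycle, cycle_fraction_of_year) {
  stopifnot(is.numeric(p_cycle), is.numeric(cycle_fraction_of_year))
  if (any(p_cycle < 0 | p_cycle > 1)) stop("'p_cycle' must be in [0, 1]")
  if (any(cycle_fraction_of_year <= 0 | cycle_fraction_of_year > 1)) {
    stop("'cycle_fraction_of_year' must be in (0, 1]")
  }
  1 - (1 - p_cycle)^(1 / cycle_fraction_of_year)
}

#' Convert an event count per person-years to an annual probability
#'
#' The colectomy inputs are reported as events per patient-years of follow-up.
#' The default reading is the simple proportion `events / person_years`
#' (which reproduces the printed derived probabilities); a constant-hazard
#' reading `1 - exp(-events / person_years)` is available via `method`.
#'
#' @param events Non-negative event count.
#' @param person_years Positive person-years at risk.
#' @param method `"proportion"` (default) or `"hazard"`.
#' @return Annual probability.
#' @export
#' @examples
#' events_per_personyears_to_annual_prob(15, 408.1) # 0.0368
#' events_per_personyears_to_annual_prob(11, 231.7) # 0.0475
events_per_personyears_to_annual_prob <- function(events, person_years,
                                                  method = c("proportion", "hazard")) {
  method <- match.arg(method)
  stopifnot(is.numeric(events), is.numeric(person_years))
  if (any(events < 0)) stop("'events' must be non-negative")
  if (any(person_years <= 0)) stop("'person_years' must be positive")
  rate <- events / person_years
  switch(method, proportion = rate, hazard = 1 - exp(-rate))
}

#' Currency conversion between PLN and EUR
#'
#' All internal accounting is in Polish zloty (PLN); euros appear only at
#' reporting time, using a fixed exchange divisor (default 4.2 PLN per euro,
#' the 2015 average).
#'
#' @param amount Amount to convert.
#' @param eur_per_pln PLN per 1 EUR (divisor), default 4.2.
#' @return Converted amount.
#' @export
#' @examples
#' pln_to_eur(44310) # ~10550
pln_to_eur <- function(amount, eur_per_pln = 4.2) {
  stopifnot(is.numeric(amount), is.numeric(eur_per_pln), eur_per_pln > 0)
  amount / eur_per_pln
}

#' @rdname pln_to_eur
#' @export
eur_to_pln <- function(amount, eur_per_pln = 4.2) {
  stopifnot(is.numeric(amount), is.numeric(eur_per_pln), eur_per_pln > 0)
  amount * eur_per_pln
}

# ---------------------------------------------------------------------------
# Model parameter container

#' Default model parameters
#'
#' Builds the full parameter set of the cost-utility model: cohort profile,
#' clinical transition inputs with their published uncertainty ranges,
#' health-state utilities, unit costs (2015 PLN), and run settings.
#'
#' Structure (class `uc_parameters`):
#' \describe{
#'   \item{cohort}{`mean_age_years`, `mean_weight_kg`, `fraction_female`.}
#'   \item{clinical}{Week-8 induction response/remission probabilities for
#'     standard care with relative risks for the biologic arm; per-cycle
#'     (8-week) gain and loss probabilities during maintenance; annual
#'     colectomy probability for standard care with the biologic-arm relative
#'     risk; post-surgery complication probability; per-cycle probability of
#'     discontinuation due to adverse events (default 0: the source trial
#'     reports comparable tolerability but no usable rate).}
#'   \item{utilities}{State utilities in `[0, 1]`.}
#'   \item{costs}{Unit costs in PLN; `eur_per_pln` exchange divisor.}
#'   \item{settings}{Horizon, discount rates, treatment cap, cycle structure,
#'     seed.}
#'   \item{bounds}{Data frame of published low/high bounds (95% CI or
#'     min/max) used by the sensitivity analyses; `NA` where no bound was
#'     published on that side.}
#' }
#'
#' @return An object of class `uc_parameters`.
#' @export
default_parameters <- function() {
  params <- structure(list(
    cohort = list(
      mean_age_years = 39.60,
      mean_weight_kg = 75.37,
      fraction_female = 0.427
    ),
    clinical = list(
      soc_response_wk8 = 0.25,
      rr_response_wk8 = 1.34,
      soc_remission_wk8 = 0.09,
      rr_remission_wk8 = 1.77,
      soc_response_percycle = 0.016,
      rr_response_percycle = 1.32,
      soc_remission_percycle = 0.014,
      rr_remission_percycle = 2.03,
      loss_response_percycle_ada = 0.161,
      loss_response_percycle_soc = 0.158,
      loss_remission_percycle_ada = 0.000,
      loss_remission_percycle_soc = 0.016,
      surgery_annual_soc = 0.0475,
      rr_surgery_ada = 0.77,
      complication_prob = 0.53,
      ae_discontinuation_percycle = 0
    ),
    utilities = list(
      active_treatment = 0.420,
      remission = 0.880,
      response = 0.760,
      remission_after_surgery = 0.610,
      complications_after_surgery = 0.420
    ),
    costs = list(
      ada_price_per_mg = 54.55,
      azathioprine_per_mg = 0.0107,
      prednisolone_per_mg = 0.1055,
      mesalazine_per_mg = 0.0015,
      mercaptopurine_per_mg = 0.0166,
      monitoring_per_8wk = 121.56,
      monitoring_per_1wk = 15.20,
      administration_once = 468.00,
      surgery = 12480,
      complication_treatment = 4160,
      standard_care_per_8wk = 204.32,
      standard_care_per_1wk = 25.54,
      indirect_annual_remission = 6523.75,
      indirect_annual_active = 22934.58,
      eur_per_pln = 4.2
    ),
    settings = list(
      horizon_years = 30,
      discount_rate_costs = 0.05,
      discount_rate_effects = 0.035,
      treatment_cap_weeks = 52,
      induction_weeks = 8L,
      maintenance_cycle_weeks = 8L,
      seed = 1L
    ),
    bounds = NULL
  ), class = "uc_parameters")

  params$bounds <- data.frame(
    parameter = c(
      "clinical.rr_response_wk8", "clinical.soc_response_wk8",
      "clinical.rr_remission_wk8", "clinical.soc_remission_wk8",
      "clinical.soc_response_percycle", "clinical.rr_response_percycle",
      "clinical.soc_remission_percycle", "clinical.rr_remission_percycle",
      "clinical.complication_prob", "clinical.rr_surgery_ada",
      "utilities.active_treatment", "utilities.remission",
      "utilities.response", "utilities.complications_after_surgery",
      "costs.surgery"
    ),
    low = c(1.02, 0.20, 1.10, 0.06, 0.010, 0.80, 0.009, 1.24,
            0.27, 0.33, 0.320, 0.790, 0.580, NA, 6240),
    high = c(1.77, 0.31, 2.86, 0.13, 0.023, 2.18, 0.020, 3.32,
             0.53, 1.86, NA, 0.910, 0.940, 0.490, 37440),
    stringsAsFactors = FALSE
  )
  flat <- unlist(lapply(.param_groups, function(g) {
    paste(g, names(params[[g]]), sep = ".")
  }))
  params$bounds <- params$bounds[order(match(params$bounds$parameter, flat)), ]
  rownames(params$bounds) <- NULL
  params
}

#' Get or set a parameter by dotted path
#'
#' Parameters are addressed as `"group.name"`, e.g.
#' `"clinical.soc_response_wk8"` or `"costs.surgery"`, matching the
#' `parameter` column of `params$bounds`.
#'
#' @param params A `uc_parameters` object.
#' @param name Dotted parameter path.
#' @param value Replacement value (for `param_set`).
#' @return `param_get` returns the value; `param_set` the modified object.
#' @export
param_get <- function(params, name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || is.null(params[[parts[1]]]) ||
      !parts[2] %in% names(params[[parts[1]]])) {
    stop("unknown parameter: ", name)
  }
  params[[parts[1]]][[parts[2]]]
}

#' @rdname param_get
#' @export
param_set <- function(params, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || is.null(params[[parts[1]]]) ||
      !parts[2] %in% names(params[[parts[1]]])) {
    stop("unknown parameter: ", name)
  }
  params[[parts[1]]][[parts[2]]] <- value
  params
}

#' Validate a model parameter set
#'
#' Checks every container invariant: probabilities in `[0, 1]`, positive
#' relative risks, utility ordering (remission >= response >= active
#' treatment), non-negative costs, indirect cost ordering, run-settings
#' sanity, and that for each arm the week-8 response + remission
#' probabilities (after relative-risk scaling and capping) sum to at most 1.
#'
#' Violations are returned as data, not raised, so that sensitivity-analysis
#' draws can be screened cheaply.
#'
#' @param params A `uc_parameters` object.
#' @param check_utility_order Enforce `remission >= response >=
#'   active_treatment`? This holds for the point estimates and is required of
#'   probabilistic draws, but the published one-way ranges deliberately cross
#'   it (the response utility's upper bound exceeds the remission point
#'   value), so deterministic sweeps relax it.
#' @return Character vector of violation messages, empty when valid.
#' @export
validate_parameters <- function(params, check_utility_order = TRUE) {
  v <- character(0)
  cl <- params$clinical
  ut <- params$utilities
  co <- params$costs
  st <- params$settings

  prob_fields <- c(
    "soc_response_wk8", "soc_remission_wk8", "soc_response_percycle",
    "soc_remission_percycle", "loss_response_percycle_ada",
    "loss_response_percycle_soc", "loss_remission_percycle_ada",
    "loss_remission_percycle_soc", "surgery_annual_soc",
    "complication_prob", "ae_discontinuation_percycle"
  )
  for (f in prob_fields) {
    x <- cl[[f]]
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      v <- c(v, sprintf("clinical.%s must be a probability in [0, 1]", f))
    }
  }
  for (f in grep("^rr_", names(cl), value = TRUE)) {
    x <- cl[[f]]
    if (!is.numeric(x) || is.na(x) || x <= 0) {
      v <- c(v, sprintf("clinical.%s must be a positive relative risk", f))
    }
  }

  # week-8 allocation must be a sub-distribution in both arms
  for (arm in c("soc", "ada")) {
    rr_resp <- if (arm == "ada") cl$rr_response_wk8 else 1
    rr_rem <- if (arm == "ada") cl$rr_remission_wk8 else 1
    ok_inputs <- is.numeric(cl$soc_response_wk8) && is.numeric(cl$soc_remission_wk8) &&
      !is.na(cl$soc_response_wk8) && !is.na(cl$soc_remission_wk8) &&
      cl$soc_response_wk8 >= 0 && cl$soc_response_wk8 <= 1 &&
      cl$soc_remission_wk8 >= 0 && cl$soc_remission_wk8 <= 1 &&
      is.numeric(rr_resp) && is.numeric(rr_rem) && rr_resp > 0 && rr_rem > 0
    if (ok_inputs) {
      total <- min(cl$soc_response_wk8 * rr_resp, 1) +
        min(cl$soc_remission_wk8 * rr_rem, 1)
      if (total > 1 + 1e-12) {
        v <- c(v, sprintf(
          "week-8 response + remission exceeds 1 in the %s arm (%.4f): check soc_response_wk8/soc_remission_wk8%s",
          arm, total, if (arm == "ada") " and their relative risks" else ""
        ))
      }
    }
  }

  for (f in names(ut)) {
    x <- ut[[f]]
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1) {
      v <- c(v, sprintf("utilities.%s must be in [0, 1]", f))
    }
  }
  if (check_utility_order &&
      is.numeric(ut$remission) && is.numeric(ut$response) &&
      is.numeric(ut$active_treatment) &&
      !(ut$remission >= ut$response && ut$response >= ut$active_treatment)) {
    v <- c(v, "utilities must satisfy remission >= response >= active_treatment")
  }

  for (f in names(co)) {
    x <- co[[f]]
    if (!is.numeric(x) || is.na(x) || x < 0) {
      v <- c(v, sprintf("costs.%s must be non-negative", f))
    }
  }
  if (is.numeric(co$indirect_annual_active) && is.numeric(co$indirect_annual_remission) &&
      co$indirect_annual_active <= co$indirect_annual_remission) {
    v <- c(v, "costs.indirect_annual_active must exceed costs.indirect_annual_remission")
  }

  if (!is.numeric(st$horizon_years) || st$horizon_years <= 0 ||
      round(st$horizon_years * 52) < st$induction_weeks) {
    v <- c(v, "settings.horizon_years must at least cover the induction phase")
  }
  for (f in c("discount_rate_costs", "discount_rate_effects")) {
    if (!is.numeric(st[[f]]) || is.na(st[[f]]) || st[[f]] < 0) {
      v <- c(v, sprintf("settings.%s must be a non-negative rate", f))
    }
  }
  if (!is.numeric(st$treatment_cap_weeks) ||
      st$treatment_cap_weeks < st$induction_weeks) {
    v <- c(v, "settings.treatment_cap_weeks must cover the induction phase")
  }

  ch <- params$cohort
  if (!is.numeric(ch$mean_age_years) || ch$mean_age_years <= 18) {
    v <- c(v, "cohort.mean_age_years must exceed 18")
  }
  if (!is.numeric(ch$fraction_female) || ch$fraction_female < 0 ||
      ch$fraction_female > 1) {
    v <- c(v, "cohort.fraction_female must be in [0, 1]")
  }
  v
}

# ---------------------------------------------------------------------------
# Configuration file I/O (YAML)

.param_groups <- c("cohort", "clinical", "utilities", "costs", "settings")

#' Read and write model parameter files
#'
#' The configuration file is YAML with five groups (`cohort`, `clinical`,
#' `utilities`, `costs`, `settings`); each leaf is either a bare number or a
#' mapping `{value, low, high}` carrying the published uncertainty range.
#' Unknown groups or keys are errors, so typos cannot silently fall back to
#' defaults. Files written by [write_parameters()] read back identically.
#'
#' @param path File path.
#' @param params A `uc_parameters` object.
#' @return `read_parameters` returns a validated `uc_parameters` object;
#'   `write_parameters` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  ref <- default_parameters()
  unknown_groups <- setdiff(names(raw), .param_groups)
  if (length(unknown_groups)) {
    stop("unknown parameter group(s): ", paste(unknown_groups, collapse = ", "))
  }
  params <- ref
  bounds <- ref$bounds[0, ]
  for (g in .param_groups) {
    grp <- raw[[g]]
    if (is.null(grp)) stop("missing parameter group: ", g)
    unknown <- setdiff(names(grp), names(ref[[g]]))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in '%s': %s", g, paste(unknown, collapse = ", ")))
    }
    missing <- setdiff(names(ref[[g]]), names(grp))
    if (length(missing)) {
      stop(sprintf("missing key(s) in '%s': %s", g, paste(missing, collapse = ", ")))
    }
    for (k in names(grp)) {
      leaf <- grp[[k]]
      if (is.list(leaf)) {
        extra <- setdiff(names(leaf), c("value", "low", "high"))
        if (length(extra)) {
          stop(sprintf("unknown field(s) in '%s.%s': %s", g, k,
                       paste(extra, collapse = ", ")))
        }
        if (is.null(leaf$value)) stop(sprintf("'%s.%s' has no value", g, k))
        params[[g]][[k]] <- as.numeric(leaf$value)
        if (!is.null(leaf$low) || !is.null(leaf$high)) {
          bounds <- rbind(bounds, data.frame(
            parameter = paste(g, k, sep = "."),
            low = if (is.null(leaf$low)) NA_real_ else leaf$low,
            high = if (is.null(leaf$high)) NA_real_ else leaf$high,
            stringsAsFactors = FALSE
          ))
        }
      } else {
        params[[g]][[k]] <- as.numeric(leaf)
      }
    }
  }
  # keep integer-typed settings stable across YAML round trips
  for (k in c("induction_weeks", "maintenance_cycle_weeks", "seed")) {
    params$settings[[k]] <- as.integer(params$settings[[k]])
  }
  # canonical row order: group order, then key order within each group
  flat <- unlist(lapply(.param_groups, function(g) {
    paste(g, names(ref[[g]]), sep = ".")
  }))
  params$bounds <- bounds[order(match(bounds$parameter, flat)), ]
  rownames(params$bounds) <- NULL
  viol <- validate_parameters(params)
  if (length(viol)) {
    stop("invalid parameter file:\n  - ", paste(viol, collapse = "\n  - "))
  }
  params
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "uc_parameters"))
  out <- list()
  for (g in .param_groups) {
    out[[g]] <- list()
    for (k in names(params[[g]])) {
      full <- paste(g, k, sep = ".")
      i <- match(full, params$bounds$parameter)
      if (!is.na(i)) {
        leaf <- list(value = params[[g]][[k]])
        if (!is.na(params$bounds$low[i])) leaf$low <- params$bounds$low[i]
        if (!is.na(params$bounds$high[i])) leaf$high <- params$bounds$high[i]
        out[[g]][[k]] <- leaf
      } else {
        out[[g]][[k]] <- params[[g]][[k]]
      }
    }
  }
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}
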