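#' Discount factor
#'
#' Compound annual discounting, continuous in time: `(1 + rate)^(-t)`.
#' State membership is valued at cycle start (no half-cycle correction by
#' default), so `t` is the cycle start time in years.
#'
#' @param annual_rate Non-negative annual discount rate.
#' @param time_years Non-negative time in years.
#' @return Discount factor in `(0, 1]`.
#' @export
#' @examples
#' discount_factor(0.05, 1) # 1/1.05
discount_factor <- function(annual_rate, time_years) {
  stopifnot(annual_rate >= 0, all(time_years >= 0))
  (1 + annual_rate)^(-time_years)
}

#' Adalimumab milligrams dosed in a week window
#'
#' Dosing calendar: 160 mg at week 0, 80 mg at week 2, then 40 mg every
#' other week from week 4 while treatment continues. A dose is given when its
#' week falls inside `[start_week, end_week)` and below the treatment cap.
#'
#' @param start_week,end_week Window bounds in weeks from model entry.
#' @param cap_weeks Treatment cap in weeks (`Inf` for unlimited).
#' @return Total mg dosed in the window.
#' @export
#' @examples
#' adalimumab_mg_in_window(0, 8) # 160 + 80 + 40 + 40 = 320
adalimumab_mg_in_window <- function(start_week, end_week, cap_weeks = Inf) {
  stopifnot(end_week >= start_week)
  hi <- min(end_week, cap_weeks)
  if (hi <= start_week) return(0)
  dose_weeks <- seq(0, max(2 * floor((hi - 1e-9) / 2), 0), by = 2)
  dose_weeks <- dose_weeks[dose_weeks >= start_week & dose_weeks < hi]
  if (!length(dose_weeks)) return(0)
  mg <- ifelse(dose_weeks == 0, 160, ifelse(dose_weeks == 2, 80, 40))
  sum(mg)
}

.pharma_states <- c("INDUCTION", "RESPONSE_ON_TX", "REMISSION_ON_TX",
                    "RESPONSE_SOC", "REMISSION_SOC", "ACTIVE_DISEASE")
.responder_states <- c("RESPONSE_ON_TX", "REMISSION_ON_TX",
                       "RESPONSE_SOC", "REMISSION_SOC")

#' Per-state, per-cycle cost components
#'
#' Undiscounted PLN cost of one unit of cohort occupancy in `state` for one
#' cycle, split by category. Components: biologic drug (mg dosed in the
#' cycle's week window while on biologic, `INDUCTION` and on-treatment states
#' only), administration (one-off at biologic initiation), monitoring (every
#' alive state, per cycle length), standard care (states under
#' pharmacological management), surgery and complication treatment (one-off
#' on entry into their transient states, so charged per unit of occupancy),
#' and - under the societal perspective - indirect costs (remission-level
#' yearly cost for response/remission states, active-level for every other
#' alive state).
#'
#' @param state One of [health_states()].
#' @param arm `"ada"` or `"soc"`.
#' @param on_biologic Do biologic dosing/dynamics apply this cycle?
#' @param start_week,length_weeks Cycle window.
#' @param costs The `costs` element of a `uc_parameters` object.
#' @param perspective `"payer"` or `"social"`.
#' @param cap_weeks Treatment cap in weeks.
#' @param psr_indirect_as_remission Charge the post-surgery remission state
#'   at the remission-level indirect cost instead of active-level.
#' @return Named numeric vector of PLN cost components.
#' @export
cost_components <- function(state, arm, on_biologic, start_week, length_weeks,
                            costs, perspective = c("payer", "social"),
                            cap_weeks = Inf,
                            psr_indirect_as_remission = FALSE) {
  perspective <- match.arg(perspective)
  stopifnot(state %in% health_states())
  out <- c(biologic_drug = 0, administration = 0, standard_care = 0,
           monitoring = 0, surgery = 0, complications = 0, indirect = 0)
  if (state == "DEATH") return(out)

  weekly <- length_weeks == 1
  out["monitoring"] <- if (weekly) costs$monitoring_per_1wk else costs$monitoring_per_8wk
  if (state %in% .pharma_states) {
    out["standard_care"] <- if (weekly) costs$standard_care_per_1wk else costs$standard_care_per_8wk
  }
  if (arm == "ada" && on_biologic &&
      state %in% c("INDUCTION", "RESPONSE_ON_TX", "REMISSION_ON_TX")) {
    mg <- adalimumab_mg_in_window(start_week, start_week + length_weeks, cap_weeks)
    out["biologic_drug"] <- mg * costs$ada_price_per_mg
    if (state == "INDUCTION" && start_week == 0) {
      out["administration"] <- costs$administration_once
    }
  }
  if (state == "SURGERY") out["surgery"] <- costs$surgery
  if (state == "POST_SURGERY_COMPLICATIONS") {
    out["complications"] <- costs$complication_treatment
  }
  if (perspective == "social") {
    remission_level <- state %in% .responder_states ||
      (psr_indirect_as_remission && state == "POST_SURGERY_REMISSION")
    annual <- if (remission_level) costs$indirect_annual_remission else costs$indirect_annual_active
    out["indirect"] <- annual * length_weeks / 52
  }
  out
}

#' Total per-state per-cycle cost
#'
#' Sum of [cost_components()] for one state-cycle under a perspective.
#'
#' @inheritParams cost_components
#' @return PLN cost per unit occupancy.
#' @export
state_cycle_cost <- function(state, arm, on_biologic, start_week, length_weeks,
                             costs, perspective = c("payer", "social"),
                             cap_weeks = Inf,
                             psr_indirect_as_remission = FALSE) {
  sum(cost_components(state, arm, on_biologic, start_week, length_weeks,
                      costs, perspective, cap_weeks,
                      psr_indirect_as_remission))
}

.state_utilities <- function(ut) {
  u <- c(
    INDUCTION = ut$active_treatment,
    RESPONSE_ON_TX = ut$response,
    REMISSION_ON_TX = ut$remission,
    RESPONSE_SOC = ut$response,
    REMISSION_SOC = ut$remission,
    ACTIVE_DISEASE = ut$active_treatment,
    SURGERY = ut$active_treatment,
    POST_SURGERY_COMPLICATIONS = ut$complications_after_surgery,
    POST_SURGERY_REMISSION = ut$remission_after_surgery,
    DEATH = 0
  )
  u[health_states()]
}

#' Accumulate discounted QALYs and costs over a trace
#'
#' Sums occupancy x utility x cycle length x discount factor for QALYs
#' (effects rate) and occupancy x unit cost x discount factor per category
#' for costs (costs rate), valuing membership at cycle start. Returns both
#' perspectives: the payer view is the direct-cost total, the societal view
#' adds indirect costs.
#'
#' @param trace A `uc_trace` from [run_cohort()].
#' @param params The `uc_parameters` object used to produce it.
#' @param half_cycle Apply a half-cycle correction (average of start and end
#'   occupancy per cycle)? Off by default.
#' @param psr_indirect_as_remission See [cost_components()].
#' @return Object of class `uc_outcome`: `qalys`, `life_years`
#'   (undiscounted), `costs_pln` (named vector of discounted category costs
#'   plus `direct_total` and `social_total`), `costs_eur`, `arm`.
#' @export
accumulate_outcomes <- function(trace, params, half_cycle = FALSE,
                                psr_indirect_as_remission = FALSE) {
  stopifnot(inherits(trace, "uc_trace"))
  sched <- trace$schedule
  n <- nrow(sched)
  occ <- trace$occupancy[seq_len(n), , drop = FALSE]
  if (half_cycle) {
    occ <- (occ + trace$occupancy[seq_len(n) + 1L, , drop = FALSE]) / 2
  }
  st <- params$settings
  co <- params$costs
  states <- health_states()
  cyc_years <- sched$length_weeks / 52
  t_years <- sched$start_week / 52
  disc_e <- discount_factor(st$discount_rate_effects, t_years)
  disc_c <- discount_factor(st$discount_rate_costs, t_years)
  alive <- setdiff(states, "DEATH")

  u <- .state_utilities(params$utilities)
  qalys <- sum(as.numeric(occ %*% u) * cyc_years * disc_e)
  life_years <- sum(rowSums(occ[, alive, drop = FALSE]) * cyc_years)

  weekly <- sched$length_weeks == 1
  occ_alive <- rowSums(occ[, alive, drop = FALSE])
  occ_pharma <- rowSums(occ[, .pharma_states, drop = FALSE])

  monitoring <- sum(occ_alive * ifelse(weekly, co$monitoring_per_1wk,
                                       co$monitoring_per_8wk) * disc_c)
  standard_care <- sum(occ_pharma * ifelse(weekly, co$standard_care_per_1wk,
                                           co$standard_care_per_8wk) * disc_c)

  biologic_drug <- 0
  administration <- 0
  if (trace$arm == "ada") {
    mg <- vapply(seq_len(n), function(i) {
      if (!sched$on_biologic[i]) return(0)
      adalimumab_mg_in_window(sched$start_week[i],
                              sched$start_week[i] + sched$length_weeks[i],
                              st$treatment_cap_weeks)
    }, numeric(1))
    # INDUCTION occupancy is nonzero only up to the assessment, so states on
    # biologic are simply INDUCTION + the on-treatment responder states
    on_drug <- occ[, "INDUCTION"] + occ[, "RESPONSE_ON_TX"] +
      occ[, "REMISSION_ON_TX"]
    biologic_drug <- sum(mg * co$ada_price_per_mg * on_drug * disc_c)
    administration <- co$administration_once * unname(occ[1, "INDUCTION"]) * disc_c[1]
  }

  surgery <- sum(occ[, "SURGERY"] * co$surgery * disc_c)
  complications <- sum(occ[, "POST_SURGERY_COMPLICATIONS"] *
                         co$complication_treatment * disc_c)

  rem_states <- .responder_states
  if (psr_indirect_as_remission) {
    rem_states <- c(rem_states, "POST_SURGERY_REMISSION")
  }
  act_states <- setdiff(alive, rem_states)
  indirect <- sum((rowSums(occ[, rem_states, drop = FALSE]) * co$indirect_annual_remission +
                     rowSums(occ[, act_states, drop = FALSE]) * co$indirect_annual_active) *
                    cyc_years * disc_c)

  costs <- c(biologic_drug = biologic_drug, administration = administration,
             standard_care = standard_care, monitoring = monitoring,
             surgery = surgery, complications = complications,
             indirect = indirect)
  costs["direct_total"] <- sum(costs[c("biologic_drug", "administration",
                                       "standard_care", "monitoring",
                                       "surgery", "complications")])
  costs["social_total"] <- costs[["direct_total"]] + costs[["indirect"]]

  structure(list(
    qalys = qalys,
    life_years = life_years,
    costs_pln = costs,
    costs_eur = costs / co$eur_per_pln,
    arm = trace$arm
  ), class = "uc_outcome")
}

#' Incremental cost-utility ratio
#'
#' Incremental costs (payer and societal perspectives), incremental QALYs,
#' and the corresponding ICURs for the biologic arm against standard care.
#' When the increments make a ratio meaningless (zero QALY difference, or the
#' intervention dominates / is dominated) the ratio is `NA` and a flag is set
#' instead.
#'
#' @param ada,soc `uc_outcome` objects for the two arms (identical settings).
#' @param eur_per_pln Exchange divisor for the EUR view.
#' @return Object of class `uc_cea` with PLN and EUR increments, ICURs per
#'   perspective, and a `dominance` label (`"none"`, `"dominant"`,
#'   `"dominated"`, `"undefined"`).
#' @export
icur <- function(ada, soc, eur_per_pln = 4.2) {
  stopifnot(inherits(ada, "uc_outcome"), inherits(soc, "uc_outcome"))
  dq <- ada$qalys - soc$qalys
  dc_payer <- ada$costs_pln[["direct_total"]] - soc$costs_pln[["direct_total"]]
  dc_social <- ada$costs_pln[["social_total"]] - soc$costs_pln[["social_total"]]

  ratio <- function(dc) {
    if (dq == 0) return(NA_real_)
    if (dq > 0 && dc <= 0) return(NA_real_) # dominant
    if (dq < 0 && dc >= 0) return(NA_real_) # dominated
    dc / dq
  }
  dominance <- if (dq == 0) {
    "undefined"
  } else if (dq > 0 && dc_payer <= 0 && dc_social <= 0) {
    "dominant"
  } else if (dq < 0 && dc_payer >= 0 && dc_social >= 0) {
    "dominated"
  } else {
    "none"
  }

  structure(list(
    delta_qaly = dq,
    delta_cost_payer_pln = dc_payer,
    delta_cost_social_pln = dc_social,
    delta_cost_payer_eur = dc_payer / eur_per_pln,
    delta_cost_social_eur = dc_social / eur_per_pln,
    icur_payer_pln = ratio(dc_payer),
    icur_social_pln = ratio(dc_social),
    icur_payer_eur = ratio(dc_payer) / eur_per_pln,
    icur_social_eur = ratio(dc_social) / eur_per_pln,
    dominance = dominance
  ), class = "uc_cea")
}

#' Run the full cost-effectiveness comparison
#'
#' Runs both arms through the cohort engine, accumulates outcomes, and
#' computes the incremental results.
#'
#' @param params A validated `uc_parameters` object.
#' @param table A `uc_life_table`.
#' @inheritParams accumulate_outcomes
#' @return List with `ada`, `soc` (`uc_outcome`), `cea` (`uc_cea`) and the
#'   two traces.
#' @export
run_cea <- function(params, table, half_cycle = FALSE,
                    psr_indirect_as_remission = FALSE) {
  tr_ada <- run_cohort(params, "ada", table)
  tr_soc <- run_cohort(params, "soc", table)
  out_ada <- accumulate_outcomes(tr_ada, params, half_cycle,
                                 psr_indirect_as_remission)
  out_soc <- accumulate_outcomes(tr_soc, params, half_cycle,
                                 psr_indirect_as_remission)
  list(ada = out_ada, soc = out_soc,
       cea = icur(out_ada, out_soc, params$costs$eur_per_pln),
       trace_ada = tr_ada, trace_soc = tr_soc)
}

#' Base-case results table
#'
#' Summarises a [run_cea()] result in the shape of a published base-case
#' table: QALYs, direct cost categories, indirect and societal totals, and
#' both ICURs, with biologic-arm, standard-care and incremental columns in
#' EUR (and PLN values available via `currency`).
#'
#' @param cea_run Result of [run_cea()].
#' @param currency `"eur"` or `"pln"`.
#' @return Data frame with columns `end_point`, `ada`, `soc`, `incremental`.
#' @export
results_table <- function(cea_run, currency = c("eur", "pln")) {
  currency <- match.arg(currency)
  ada <- cea_run$ada
  soc <- cea_run$soc
  cost <- function(o) if (currency == "eur") o$costs_eur else o$costs_pln
  rows <- list(
    c("QALY", ada$qalys, soc$qalys),
    c("Total direct costs", cost(ada)[["direct_total"]], cost(soc)[["direct_total"]]),
    c("Adalimumab costs (drug + administration)",
      cost(ada)[["biologic_drug"]] + cost(ada)[["administration"]],
      cost(soc)[["biologic_drug"]] + cost(soc)[["administration"]]),
    c("Standard care costs", cost(ada)[["standard_care"]], cost(soc)[["standard_care"]]),
    c("Monitoring costs", cost(ada)[["monitoring"]], cost(soc)[["monitoring"]]),
    c("Colectomy costs", cost(ada)[["surgery"]], cost(soc)[["surgery"]]),
    c("Complication costs", cost(ada)[["complications"]], cost(soc)[["complications"]]),
    c("Colectomy + complication costs",
      cost(ada)[["surgery"]] + cost(ada)[["complications"]],
      cost(soc)[["surgery"]] + cost(soc)[["complications"]]),
    c("Total indirect costs", cost(ada)[["indirect"]], cost(soc)[["indirect"]]),
    c("Total direct and indirect costs",
      cost(ada)[["social_total"]], cost(soc)[["social_total"]])
  )
  df <- data.frame(
    end_point = vapply(rows, `[[`, character(1), 1),
    ada = as.numeric(vapply(rows, `[[`, character(1), 2)),
    soc = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  df$incremental <- df$ada - df$soc
  icur_rows <- data.frame(
    end_point = c("ICUR - public payer perspective", "ICUR - social perspective"),
    ada = NA_real_, soc = NA_real_,
    incremental = if (currency == "eur") {
      c(cea_run$cea$icur_payer_eur, cea_run$cea$icur_social_eur)
    } else {
      c(cea_run$cea$icur_payer_pln, cea_run$cea$icur_social_pln)
    },
    stringsAsFactors = FALSE
  )
  rbind(df, icur_rows)
}

#' Write a results table to CSV
#'
#' @param cea_run Result of [run_cea()].
#' @param path Output path.
#' @export
write_results_csv <- function(cea_run, path) {
  eur <- results_table(cea_run, "eur")
  pln <- results_table(cea_run, "pln")
  names(pln)[2:4] <- paste0(names(pln)[2:4], "_pln")
  out <- cbind(eur, pln[, 2:4])
  names(out)[2:4] <- paste0(names(out)[2:4], "_eur")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
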