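#' Health states of the cohort model
#'
#' Ten states. `INDUCTION` holds the whole cohort during the weekly induction
#' cycles. Responders continue treatment in `RESPONSE_ON_TX` /
#' `REMISSION_ON_TX` (biologic arm while the treatment cap allows) or
#' `RESPONSE_SOC` / `REMISSION_SOC` (standard care). Treatment failures sit in
#' `ACTIVE_DISEASE`, from which colectomy (`SURGERY`) is reachable. Surgery
#' leads either to transient `POST_SURGERY_COMPLICATIONS` (resolved within one
#' 8-week cycle) or directly to `POST_SURGERY_REMISSION`, which exits only to
#' `DEATH`. `DEATH` is absorbing and is reached from every alive state with
#' the same background probability.
#'
#' @return Character vector of state names, in trace column order.
#' @export
health_states <- function() {
  c("INDUCTION", "RESPONSE_ON_TX", "REMISSION_ON_TX", "RESPONSE_SOC",
    "REMISSION_SOC", "ACTIVE_DISEASE", "SURGERY",
    "POST_SURGERY_COMPLICATIONS", "POST_SURGERY_REMISSION", "DEATH")
}

.S <- function(name) match(name, health_states())

#' Build the two-period cycle schedule
#'
#' The horizon is divided into weekly induction cycles (weeks 0 to the week-8
#' assessment) followed by 8-week maintenance cycles; a 30-year horizon
#' (1560 weeks) gives 8 + 194 = 202 cycles.
#'
#' @param settings The `settings` element of a `uc_parameters` object.
#' @return Data frame of class `uc_schedule` with columns `cycle`, `phase`
#'   (`"induction"`/`"maintenance"`), `start_week`, `length_weeks`.
#' @export
build_schedule <- function(settings) {
  horizon_weeks <- round(settings$horizon_years * 52)
  ind <- settings$induction_weeks
  mlen <- settings$maintenance_cycle_weeks
  if (horizon_weeks < ind) {
    stop("horizon shorter than the induction phase (", ind, " weeks)")
  }
  n_maint <- ceiling((horizon_weeks - ind) / mlen)
  sched <- data.frame(
    cycle = seq_len(ind + n_maint),
    phase = c(rep("induction", ind), rep("maintenance", n_maint)),
    start_week = c(seq_len(ind) - 1, ind + mlen * (seq_len(n_maint) - 1)),
    length_weeks = c(rep(1, ind), rep(mlen, n_maint)),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("uc_schedule", "data.frame")
  sched
}

#' Allocation of the cohort at the week-8 assessment
#'
#' Induction outcome probabilities: remission and response (exclusive of
#' remission) for the given arm, with the biologic arm obtained by
#' relative-risk scaling of the standard-care probabilities; the remainder is
#' treatment failure.
#'
#' @param clin The `clinical` element of a `uc_parameters` object.
#' @param arm `"ada"` or `"soc"`.
#' @return Named numeric vector `c(remission, response, failure)`.
#' @export
#' @examples
#' induction_allocation(default_parameters()$clinical, "soc")
induction_allocation <- function(clin, arm = c("ada", "soc")) {
  arm <- match.arg(arm)
  rr_resp <- if (arm == "ada") clin$rr_response_wk8 else 1
  rr_rem <- if (arm == "ada") clin$rr_remission_wk8 else 1
  remission <- apply_relative_risk(clin$soc_remission_wk8, rr_rem)
  response <- apply_relative_risk(clin$soc_response_wk8, rr_resp)
  if (remission + response > 1 + 1e-12) {
    stop("week-8 remission + response exceeds 1 in the ", arm, " arm")
  }
  c(remission = remission, response = response,
    failure = max(1 - remission - response, 0))
}

#' Per-cycle colectomy probability for an arm
#'
#' The annual standard-care colectomy probability is scaled by the biologic
#' relative risk (biologic arm, while arm-specific dynamics apply) and then
#' converted to the cycle length under a constant hazard.
#'
#' @inheritParams induction_allocation
#' @param on_biologic Do biologic-arm dynamics apply this cycle?
#' @param cycle_length_weeks Cycle length in weeks.
#' @return Probability of colectomy within the cycle, from active disease.
#' @export
surgery_cycle_prob <- function(clin, arm, on_biologic, cycle_length_weeks) {
  annual <- clin$surgery_annual_soc
  if (arm == "ada" && on_biologic) {
    annual <- apply_relative_risk(annual, clin$rr_surgery_ada)
  }
  annual_prob_to_cycle(annual, cycle_length_weeks / 52)
}

#' Maintenance-cycle transition matrix
#'
#' Row-stochastic matrix over the ten health states for one maintenance
#' cycle. Background death is applied first to every alive state; surviving
#' mass then undergoes, in order: discontinuation for adverse events (on
#' biologic only), loss of response/remission to `ACTIVE_DISEASE`, and from
#' `ACTIVE_DISEASE` colectomy, then remission gain, then response gain, each
#' event drawing on the mass left by the previous one. With `on_biologic =
#' FALSE` the biologic arm faces exactly the standard-care dynamics, and any
#' mass still in on-treatment states drains to the standard-care response/
#' remission states (treatment-cap hand-over).
#'
#' @inheritParams surgery_cycle_prob
#' @param death_p Per-cycle background death probability.
#' @return 10 x 10 row-stochastic matrix with dimnames [health_states()].
#' @export
maintenance_transition_matrix <- function(clin, arm = c("ada", "soc"),
                                          on_biologic = FALSE, death_p = 0,
                                          cycle_length_weeks = 8) {
  arm <- match.arg(arm)
  stopifnot(death_p >= 0, death_p <= 1)
  states <- health_states()
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  biologic <- arm == "ada" && on_biologic

  loss_resp <- if (biologic) clin$loss_response_percycle_ada else clin$loss_response_percycle_soc
  loss_rem <- if (biologic) clin$loss_remission_percycle_ada else clin$loss_remission_percycle_soc
  p_surg <- surgery_cycle_prob(clin, arm, on_biologic, cycle_length_weeks)
  p_rem_gain <- clin$soc_remission_percycle   # regained on standard care in both arms
  p_resp_gain <- clin$soc_response_percycle
  ae <- if (biologic) clin$ae_discontinuation_percycle else 0
  compl <- clin$complication_prob
  s <- 1 - death_p

  set_row <- function(state, targets) {
    M[state, "DEATH"] <<- death_p
    for (t in names(targets)) M[state, t] <<- M[state, t] + s * targets[[t]]
  }

  set_row("INDUCTION", list(INDUCTION = 1))
  if (biologic) {
    set_row("RESPONSE_ON_TX", list(
      RESPONSE_SOC = ae,
      ACTIVE_DISEASE = (1 - ae) * loss_resp,
      RESPONSE_ON_TX = (1 - ae) * (1 - loss_resp)
    ))
    set_row("REMISSION_ON_TX", list(
      REMISSION_SOC = ae,
      ACTIVE_DISEASE = (1 - ae) * loss_rem,
      REMISSION_ON_TX = (1 - ae) * (1 - loss_rem)
    ))
  } else {
    # off-biologic hand-over: on-treatment states behave as (and move to)
    # their standard-care counterparts
    set_row("RESPONSE_ON_TX", list(
      ACTIVE_DISEASE = loss_resp, RESPONSE_SOC = 1 - loss_resp
    ))
    set_row("REMISSION_ON_TX", list(
      ACTIVE_DISEASE = loss_rem, REMISSION_SOC = 1 - loss_rem
    ))
  }
  set_row("RESPONSE_SOC", list(
    ACTIVE_DISEASE = clin$loss_response_percycle_soc,
    RESPONSE_SOC = 1 - clin$loss_response_percycle_soc
  ))
  set_row("REMISSION_SOC", list(
    ACTIVE_DISEASE = clin$loss_remission_percycle_soc,
    REMISSION_SOC = 1 - clin$loss_remission_percycle_soc
  ))
  set_row("ACTIVE_DISEASE", list(
    SURGERY = p_surg,
    REMISSION_SOC = (1 - p_surg) * p_rem_gain,
    RESPONSE_SOC = (1 - p_surg) * (1 - p_rem_gain) * p_resp_gain,
    ACTIVE_DISEASE = (1 - p_surg) * (1 - p_rem_gain) * (1 - p_resp_gain)
  ))
  set_row("SURGERY", list(
    POST_SURGERY_COMPLICATIONS = compl,
    POST_SURGERY_REMISSION = 1 - compl
  ))
  set_row("POST_SURGERY_COMPLICATIONS", list(POST_SURGERY_REMISSION = 1))
  set_row("POST_SURGERY_REMISSION", list(POST_SURGERY_REMISSION = 1))
  M["DEATH", "DEATH"] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("internal error: transition matrix rows do not sum to 1")
  }
  M
}

#' Run the cohort simulation for one arm
#'
#' Deterministic cohort propagation. The cohort enters at the mean cohort age,
#' 100% in `INDUCTION`; during the weekly induction cycles only background
#' death acts. Treatment response is assessed after the ninth cycle - the
#' first 8-week cycle, through which the whole surviving cohort remains in
#' `INDUCTION` on its induction regimen - and survivors are then allocated by
#' [induction_allocation()], with failures split between `ACTIVE_DISEASE` and
#' immediate `SURGERY` by the cycle colectomy probability. (If the horizon
#' ends at the induction boundary the allocation is applied there instead, so
#' an 8-week run ends in the allocation distribution.) Subsequent maintenance
#' cycles apply [maintenance_transition_matrix()], with biologic-arm dynamics
#' for cycles whose start week is below the treatment cap. Ageing is
#' continuous: age = entry age + elapsed weeks / 52.
#'
#' @param params A validated `uc_parameters` object.
#' @param arm `"ada"` or `"soc"`.
#' @param table A `uc_life_table` covering the cohort's age range.
#' @return Object of class `uc_trace`: list with `occupancy` (rows = each
#'   cycle start plus a terminal row at the horizon; columns =
#'   [health_states()]), `schedule` (with an `on_biologic` flag per cycle),
#'   `arm`, `entry_age`.
#' @export
run_cohort <- function(params, arm = c("ada", "soc"), table) {
  arm <- match.arg(arm)
  # utility ordering is relaxed here so sensitivity sweeps over published
  # ranges (which cross it at the extremes) can run
  viol <- validate_parameters(params, check_utility_order = FALSE)
  if (length(viol)) {
    stop("invalid parameters:\n  - ", paste(viol, collapse = "\n  - "))
  }
  sched <- build_schedule(params$settings)
  cap <- params$settings$treatment_cap_weeks
  sched$on_biologic <- arm == "ada" & sched$start_week < cap
  states <- health_states()
  n_states <- length(states)
  n_cycles <- nrow(sched)
  age0 <- params$cohort$mean_age_years
  death_i <- .S("DEATH")
  alive_i <- setdiff(seq_len(n_states), death_i)

  occ <- matrix(0, n_cycles + 1L, n_states, dimnames = list(NULL, states))
  occ[1, "INDUCTION"] <- 1

  # cache no-death matrices; death is injected per cycle
  M0 <- list(
    on = maintenance_transition_matrix(params$clinical, arm, TRUE, 0,
                                       params$settings$maintenance_cycle_weeks),
    off = maintenance_transition_matrix(params$clinical, arm, FALSE, 0,
                                        params$settings$maintenance_cycle_weeks)
  )

  # response is assessed after the ninth cycle (end of the first 8-week
  # cycle); a horizon ending at the induction boundary assesses there
  assess_cycle <- min(params$settings$induction_weeks + 1L, n_cycles)

  # vectorised death-probability lookup (run per draw in the PSA)
  ages <- floor(age0 + sched$start_week / 52)
  qx_i <- match(ages, table$age)
  if (anyNA(qx_i)) {
    stop(sprintf(
      "ages %g-%g exceed the life table (ages %d-%d); extend the table past the model horizon",
      min(ages), max(ages), table$age[1], table$age[nrow(table)]
    ))
  }
  death_p <- 1 - (1 - table$qx[qx_i])^(sched$length_weeks / 52)

  for (i in seq_len(n_cycles)) {
    cur <- occ[i, ]
    d <- death_p[i]
    surv <- cur[alive_i] * (1 - d)
    dead <- cur[death_i] + sum(cur[alive_i]) * d

    if (i <= assess_cycle) {
      # whole cohort still in INDUCTION; only background death acts
      nxt <- cur
      nxt[alive_i] <- surv
      nxt[death_i] <- dead
      if (i == assess_cycle) {
        alloc <- induction_allocation(params$clinical, arm)
        on_bio_next <- arm == "ada" &&
          (sched$start_week[i] + sched$length_weeks[i]) < cap
        p_surg <- surgery_cycle_prob(params$clinical, arm, on_bio_next,
                                     params$settings$maintenance_cycle_weeks)
        total_alive <- sum(nxt[alive_i])
        nxt[alive_i] <- 0
        rem_state <- if (on_bio_next) "REMISSION_ON_TX" else "REMISSION_SOC"
        resp_state <- if (on_bio_next) "RESPONSE_ON_TX" else "RESPONSE_SOC"
        nxt[rem_state] <- total_alive * alloc[["remission"]]
        nxt[resp_state] <- total_alive * alloc[["response"]]
        nxt["SURGERY"] <- total_alive * alloc[["failure"]] * p_surg
        nxt["ACTIVE_DISEASE"] <- total_alive * alloc[["failure"]] * (1 - p_surg)
      }
      occ[i + 1, ] <- nxt
    } else {
      M <- if (sched$on_biologic[i]) M0$on else M0$off
      nxt <- as.numeric(surv %*% M[alive_i, , drop = FALSE])
      nxt[death_i] <- nxt[death_i] + dead
      occ[i + 1, ] <- nxt
    }
  }

  rs <- rowSums(occ)
  if (any(abs(rs - 1) > 1e-9) || any(occ < -1e-12)) {
    stop("internal error: trace conservation violated")
  }
  structure(list(occupancy = occ, schedule = sched, arm = arm,
                 entry_age = age0),
            class = "uc_trace")
}

#' Write a cohort trace to CSV
#'
#' One row per occupancy snapshot (each cycle start plus the terminal
#' horizon row), with cycle index, start week, cycle length and one column
#' per health state. Output is deterministic for identical inputs.
#'
#' @param trace A `uc_trace`.
#' @param path Output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "uc_trace"))
  sched <- trace$schedule
  n <- nrow(sched)
  df <- data.frame(
    cycle = c(sched$cycle, NA),
    start_week = c(sched$start_week, sched$start_week[n] + sched$length_weeks[n]),
    length_weeks = c(sched$length_weeks, NA),
    trace$occupancy,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
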