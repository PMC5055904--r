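# Independent individual-level Monte-Carlo oracle for the cohort engine.
#
# Deliberately re-derives every transition from the raw parameters with
# sequential per-patient coin flips (death first, then discontinuation /
# loss / surgery / remission / response in the documented event order),
# sharing no propagation code with run_cohort. Returns state-occupancy
# fractions at the start of each requested cycle, aligned with the rows of a
# uc_trace.

microsim_occupancy <- function(params, arm, table, n_patients, seed,
                               record_rows) {
  set.seed(seed)
  states <- health_states()
  sched <- build_schedule(params$settings)
  cl <- params$clinical
  cap <- params$settings$treatment_cap_weeks
  age0 <- params$cohort$mean_age_years
  assess <- min(params$settings$induction_weeks + 1L, nrow(sched))
  mlen <- params$settings$maintenance_cycle_weeks

  s <- rep(match("INDUCTION", states), n_patients)
  DEATH <- match("DEATH", states)
  rec <- matrix(NA_real_, length(record_rows), length(states),
                dimnames = list(NULL, states))
  snap <- function(row) {
    k <- match(row, record_rows)
    if (!is.na(k)) rec[k, ] <<- tabulate(s, length(states)) / n_patients
  }
  snap(1L)

  cyc_surg <- function(on_bio) {
    ann <- cl$surgery_annual_soc
    if (arm == "ada" && on_bio) ann <- min(ann * cl$rr_surgery_ada, 1)
    1 - (1 - ann)^(mlen / 52)
  }

  for (i in seq_len(nrow(sched))) {
    wk <- sched$start_week[i]
    len <- sched$length_weeks[i]
    qx <- table$qx[match(floor(age0 + wk / 52), table$age)]
    d <- 1 - (1 - qx)^(len / 52)
    on_bio <- arm == "ada" && wk < cap

    alive <- s != DEATH
    dies <- alive & stats::runif(n_patients) < d
    s[dies] <- DEATH
    alive <- s != DEATH

    if (i < assess) {
      # induction: death only
    } else if (i == assess) {
      idx <- which(alive)
      rr_resp <- if (arm == "ada") cl$rr_response_wk8 else 1
      rr_rem <- if (arm == "ada") cl$rr_remission_wk8 else 1
      p_rem <- min(cl$soc_remission_wk8 * rr_rem, 1)
      p_resp <- min(cl$soc_response_wk8 * rr_resp, 1)
      on_bio_next <- arm == "ada" && (wk + len) < cap
      u <- stats::runif(length(idx))
      rem <- u < p_rem
      resp <- !rem & u < p_rem + p_resp
      fail <- !rem & !resp
      s[idx[rem]] <- match(if (on_bio_next) "REMISSION_ON_TX" else "REMISSION_SOC", states)
      s[idx[resp]] <- match(if (on_bio_next) "RESPONSE_ON_TX" else "RESPONSE_SOC", states)
      fi <- idx[fail]
      surg <- stats::runif(length(fi)) < cyc_surg(on_bio_next)
      s[fi[surg]] <- match("SURGERY", states)
      s[fi[!surg]] <- match("ACTIVE_DISEASE", states)
    } else {
      nxt <- s
      at <- function(name) which(alive & s == match(name, states))

      if (arm == "ada" && on_bio) {
        ae <- cl$ae_discontinuation_percycle
        for (pair in list(c("RESPONSE_ON_TX", "RESPONSE_SOC",
                            cl$loss_response_percycle_ada),
                          c("REMISSION_ON_TX", "REMISSION_SOC",
                            cl$loss_remission_percycle_ada))) {
          idx <- at(pair[1])
          disc <- stats::runif(length(idx)) < ae
          lost <- !disc & stats::runif(length(idx)) < as.numeric(pair[3])
          nxt[idx[disc]] <- match(pair[2], states)
          nxt[idx[lost]] <- match("ACTIVE_DISEASE", states)
        }
      } else {
        # off biologic: on-treatment states follow standard-care dynamics
        # and land in the standard-care states
        for (pair in list(c("RESPONSE_ON_TX", "RESPONSE_SOC",
                            cl$loss_response_percycle_soc),
                          c("REMISSION_ON_TX", "REMISSION_SOC",
                            cl$loss_remission_percycle_soc))) {
          idx <- at(pair[1])
          lost <- stats::runif(length(idx)) < as.numeric(pair[3])
          nxt[idx[lost]] <- match("ACTIVE_DISEASE", states)
          nxt[idx[!lost]] <- match(pair[2], states)
        }
      }
      for (pair in list(c("RESPONSE_SOC", cl$loss_response_percycle_soc),
                        c("REMISSION_SOC", cl$loss_remission_percycle_soc))) {
        idx <- at(pair[1])
        lost <- stats::runif(length(idx)) < as.numeric(pair[2])
        nxt[idx[lost]] <- match("ACTIVE_DISEASE", states)
      }

      idx <- at("ACTIVE_DISEASE")
      surg <- stats::runif(length(idx)) < cyc_surg(on_bio)
      nxt[idx[surg]] <- match("SURGERY", states)
      rest <- idx[!surg]
      rem <- stats::runif(length(rest)) < cl$soc_remission_percycle
      nxt[rest[rem]] <- match("REMISSION_SOC", states)
      rest <- rest[!rem]
      resp <- stats::runif(length(rest)) < cl$soc_response_percycle
      nxt[rest[resp]] <- match("RESPONSE_SOC", states)

      idx <- at("SURGERY")
      compl <- stats::runif(length(idx)) < cl$complication_prob
      nxt[idx[compl]] <- match("POST_SURGERY_COMPLICATIONS", states)
      nxt[idx[!compl]] <- match("POST_SURGERY_REMISSION", states)

      nxt[at("POST_SURGERY_COMPLICATIONS")] <- match("POST_SURGERY_REMISSION", states)
      s <- nxt
    }
    snap(i + 1L)
  }
  rec
}
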