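# shared fixtures, built in code

base_params <- function() default_parameters()

synth_table <- local({
  tbl <- NULL
  function() {
    if (is.null(tbl)) tbl <<- synth_life_table()
    tbl
  }
})

# flat-mortality table spanning the model's age range
flat_table <- function(qx = 0, ages = 18:100) {
  life_table(ages, rep(qx, length(ages)))
}

# parameter set with every transition switched off (identity dynamics)
inert_params <- function() {
  p <- default_parameters()
  for (f in c("soc_response_percycle", "soc_remission_percycle",
              "loss_response_percycle_ada", "loss_response_percycle_soc",
              "loss_remission_percycle_ada", "loss_remission_percycle_soc",
              "surgery_annual_soc")) {
    p$clinical[[f]] <- 0
  }
  p
}

# biologic arm made dynamically identical to standard care
null_effect_params <- function() {
  p <- default_parameters()
  p$clinical$rr_response_wk8 <- 1
  p$clinical$rr_remission_wk8 <- 1
  p$clinical$rr_response_percycle <- 1
  p$clinical$rr_remission_percycle <- 1
  p$clinical$rr_surgery_ada <- 1
  p$clinical$loss_response_percycle_ada <- p$clinical$loss_response_percycle_soc
  p$clinical$loss_remission_percycle_ada <- p$clinical$loss_remission_percycle_soc
  p
}

# hand-built single-maintenance-cycle trace for accumulation checks
one_cycle_trace <- function(state, arm = "soc") {
  occ <- matrix(0, 2, 10, dimnames = list(NULL, health_states()))
  occ[, state] <- 1
  sched <- data.frame(cycle = 1L, phase = "maintenance", start_week = 0,
                      length_weeks = 8, on_biologic = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(occupancy = occ, schedule = sched, arm = arm,
                 entry_age = 39.6), class = "uc_trace")
}
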