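test_that("discount factor follows compound annual discounting", {
  expect_equal(discount_factor(0.05, 0), 1)
  expect_equal(discount_factor(0.05, 1), 1 / 1.05)
  expect_equal(discount_factor(0, 7.3), 1)
  expect_equal(discount_factor(0.035, 2.5), 1.035^-2.5)
})

test_that("the dosing calendar yields the published induction drug mass", {
  expect_equal(adalimumab_mg_in_window(0, 8), 320)
  expect_equal(adalimumab_mg_in_window(0, 8) * 54.55, 17456)
  expect_equal(adalimumab_mg_in_window(8, 16), 160)  # 4 x 40 mg
  expect_equal(adalimumab_mg_in_window(48, 56, cap_weeks = 52), 80)
  expect_equal(adalimumab_mg_in_window(56, 64, cap_weeks = 52), 0)
  expect_equal(adalimumab_mg_in_window(2, 3), 80)
  expect_equal(adalimumab_mg_in_window(1, 2), 0)
  # one year of uninterrupted treatment: 160 + 80 + 24 x 40
  expect_equal(adalimumab_mg_in_window(0, 52), 1200)
})

test_that("state-cycle costs assemble the published per-cycle components", {
  co <- base_params()$costs
  expect_equal(state_cycle_cost("DEATH", "soc", FALSE, 100, 8, co, "payer"), 0)
  expect_equal(state_cycle_cost("ACTIVE_DISEASE", "soc", FALSE, 100, 8, co, "payer"),
               204.32 + 121.56)
  expect_equal(state_cycle_cost("ACTIVE_DISEASE", "soc", FALSE, 0, 1, co, "payer"),
               25.54 + 15.20)
  # post-surgery remission: monitored, but no pharmacological standard care
  expect_equal(state_cycle_cost("POST_SURGERY_REMISSION", "soc", FALSE, 100, 8,
                                co, "payer"), 121.56)
  expect_equal(state_cycle_cost("SURGERY", "soc", FALSE, 100, 8, co, "payer"),
               12480 + 121.56)
  cc <- cost_components("POST_SURGERY_COMPLICATIONS", "soc", FALSE, 100, 8, co,
                        "social")
  expect_equal(cc[["complications"]], 4160)
  expect_equal(cc[["indirect"]], 22934.58 * 8 / 52)
  # responder states carry remission-level indirect costs
  cc <- cost_components("RESPONSE_SOC", "soc", FALSE, 100, 8, co, "social")
  expect_equal(cc[["indirect"]], 6523.75 * 8 / 52)
  # payer perspective never sees indirect costs
  for (st in health_states()) {
    expect_equal(cost_components(st, "soc", FALSE, 100, 8, co, "payer")[["indirect"]], 0)
  }
})

test_that("a single all-remission cycle accrues utility x time", {
  p <- base_params()
  p$settings$discount_rate_effects <- 0
  out <- accumulate_outcomes(one_cycle_trace("REMISSION_SOC"), p)
  expect_equal(out$qalys, 0.880 * 8 / 52)
  out <- accumulate_outcomes(one_cycle_trace("DEATH"), p)
  expect_equal(out$qalys, 0)
  expect_equal(unname(out$costs_pln[["social_total"]]), 0)
})

test_that("unit utilities without discounting recover undiscounted life-years", {
  p <- base_params()
  for (u in names(p$utilities)) p$utilities[[u]] <- 1
  p$settings$discount_rate_effects <- 0
  tr <- run_cohort(p, "soc", flat_table(0))
  out <- accumulate_outcomes(tr, p)
  expect_equal(out$qalys, 30, tolerance = 1e-9)
  expect_equal(out$life_years, 30, tolerance = 1e-9)

  # and with mortality, QALYs equal life-years exactly under the same limits
  tr <- run_cohort(p, "soc", synth_table())
  out <- accumulate_outcomes(tr, p)
  expect_equal(out$qalys, out$life_years, tolerance = 1e-9)
  expect_lt(out$life_years, 30)
})

test_that("discounted totals decrease in the discount rate", {
  lt <- synth_table()
  p <- base_params()
  qal <- cost <- numeric(0)
  for (r in c(0, 0.035, 0.05, 0.1)) {
    p$settings$discount_rate_effects <- r
    p$settings$discount_rate_costs <- r
    out <- accumulate_outcomes(run_cohort(p, "soc", lt), p)
    qal <- c(qal, out$qalys)
    cost <- c(cost, out$costs_pln[["social_total"]])
  }
  expect_true(all(diff(qal) < 0))
  expect_true(all(diff(cost) < 0))
})

test_that("category costs sum to the totals for both arms", {
  lt <- synth_table()
  p <- base_params()
  for (arm in c("ada", "soc")) {
    out <- accumulate_outcomes(run_cohort(p, arm, lt), p)
    cp <- out$costs_pln
    expect_equal(unname(cp[["direct_total"]]),
                 sum(cp[c("biologic_drug", "administration", "standard_care",
                          "monitoring", "surgery", "complications")]),
                 tolerance = 1e-6)
    expect_equal(unname(cp[["social_total"]]),
                 unname(cp[["direct_total"]] + cp[["indirect"]]),
                 tolerance = 1e-6)
    expect_equal(unname(out$costs_eur), unname(cp) / 4.2, tolerance = 1e-9)
    # QALYs can never exceed life-years at the ceiling utility
    expect_lte(out$qalys, out$life_years * 0.880)
  }
})

test_that("vectorised accumulation agrees with the per-state cost surface", {
  # dual route: rebuild the totals cell by cell from state_cycle_cost
  p <- base_params()
  p$settings$horizon_years <- 2
  lt <- synth_table()
  for (arm in c("ada", "soc")) {
    tr <- run_cohort(p, arm, lt)
    out <- accumulate_outcomes(tr, p)
    sched <- tr$schedule
    for (persp in c("payer", "social")) {
      total <- 0
      for (i in seq_len(nrow(sched))) {
        disc <- discount_factor(p$settings$discount_rate_costs,
                                sched$start_week[i] / 52)
        for (st in health_states()) {
          total <- total + unname(tr$occupancy[i, st]) * disc *
            state_cycle_cost(st, arm, sched$on_biologic[i],
                             sched$start_week[i], sched$length_weeks[i],
                             p$costs, persp,
                             cap_weeks = p$settings$treatment_cap_weeks)
        }
      }
      key <- if (persp == "payer") "direct_total" else "social_total"
      expect_equal(total, unname(out$costs_pln[[key]]), tolerance = 1e-8)
    }
  }
})

test_that("ICUR arithmetic, dominance flags and currency invariance hold", {
  mk <- function(q, direct, social) {
    structure(list(qalys = q, life_years = q,
                   costs_pln = c(direct_total = direct, social_total = social),
                   costs_eur = c(direct_total = direct, social_total = social) / 4.2,
                   arm = "x"), class = "uc_outcome")
  }
  r <- icur(mk(10.5, 4200, 4200), mk(10.0, 0, 0))
  expect_equal(r$delta_qaly, 0.5)
  expect_equal(r$icur_payer_eur, (4200 / 4.2) / 0.5)
  expect_equal(r$dominance, "none")

  r <- icur(mk(10.5, -100, -100), mk(10, 0, 0))
  expect_equal(r$dominance, "dominant")
  expect_true(is.na(r$icur_payer_eur))
  r <- icur(mk(9.5, 100, 100), mk(10, 0, 0))
  expect_equal(r$dominance, "dominated")
  r <- icur(mk(10, 100, 100), mk(10, 0, 0))
  expect_equal(r$dominance, "undefined")

  # currency invariance on a real run: PLN ICUR / 4.2 equals EUR ICUR, and
  # re-denominating every cost input in EUR leaves the ICUR unchanged
  lt <- synth_table()
  p <- base_params()
  res <- run_cea(p, lt)
  expect_equal(res$cea$icur_payer_pln / 4.2, res$cea$icur_payer_eur,
               tolerance = 1e-12)
  p_eur <- p
  for (f in setdiff(names(p$costs), "eur_per_pln")) {
    p_eur$costs[[f]] <- p$costs[[f]] / 4.2
  }
  p_eur$costs$eur_per_pln <- 1
  res_eur <- run_cea(p_eur, lt)
  expect_equal(res_eur$cea$icur_payer_eur, res$cea$icur_payer_eur,
               tolerance = 1e-9)
  expect_equal(res_eur$cea$icur_social_eur, res$cea$icur_social_eur,
               tolerance = 1e-9)
})

test_that("payer totals are blind to the indirect cost inputs", {
  lt <- synth_table()
  p <- base_params()
  base <- run_cea(p, lt)
  p$costs$indirect_annual_remission <- 1
  p$costs$indirect_annual_active <- 50000
  mod <- run_cea(p, lt)
  expect_equal(mod$cea$delta_cost_payer_eur, base$cea$delta_cost_payer_eur)
  expect_equal(mod$cea$icur_payer_eur, base$cea$icur_payer_eur)
  expect_false(isTRUE(all.equal(mod$cea$icur_social_eur,
                                base$cea$icur_social_eur)))
})

test_that("results table mirrors the outcome object and writes both currencies", {
  lt <- synth_table()
  res <- run_cea(base_params(), lt)
  tab <- results_table(res, "eur")
  expect_equal(tab$incremental[tab$end_point == "QALY"], res$cea$delta_qaly)
  expect_equal(tab$incremental[tab$end_point == "Total direct costs"],
               res$cea$delta_cost_payer_eur)
  f <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(res, f)
  back <- utils::read.csv(f)
  expect_equal(back$incremental_pln[2] / 4.2, back$incremental_eur[2],
               tolerance = 1e-9)
})
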