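#' One-way deterministic sensitivity analysis
#'
#' Each parameter carrying a published range is set to its low and then its
#' high bound with everything else at base case, and the full model is rerun
#' both times. A bound missing on one side (some ranges are printed
#' one-sided) is replaced by the base value, so the sweep never moves a
#' parameter beyond what was published.
#'
#' @param params A validated `uc_parameters` object.
#' @param table A `uc_life_table`.
#' @return Data frame with one row per parameter x perspective:
#'   `parameter`, `perspective`, `low`, `high`, `icur_at_low`,
#'   `icur_at_high` (EUR/QALY), plus `icur_base` for reference, sorted by
#'   decreasing ICUR span within perspective.
#' @export
run_owsa <- function(params, table) {
  stopifnot(inherits(params, "uc_parameters"))
  base <- run_cea(params, table)$cea
  bounds <- params$bounds
  if (is.null(bounds) || !nrow(bounds)) {
    warning("no bounded parameters; OWSA is empty")
    return(data.frame())
  }
  entries <- lapply(seq_len(nrow(bounds)), function(i) {
    name <- bounds$parameter[i]
    base_val <- param_get(params, name)
    lo <- if (is.na(bounds$low[i])) base_val else bounds$low[i]
    hi <- if (is.na(bounds$high[i])) base_val else bounds$high[i]
    cea_lo <- run_cea(param_set(params, name, lo), table)$cea
    cea_hi <- run_cea(param_set(params, name, hi), table)$cea
    data.frame(
      parameter = name,
      perspective = c("payer", "social"),
      low = lo, high = hi,
      icur_at_low = c(cea_lo$icur_payer_eur, cea_lo$icur_social_eur),
      icur_at_high = c(cea_hi$icur_payer_eur, cea_hi$icur_social_eur),
      icur_base = c(base$icur_payer_eur, base$icur_social_eur),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, entries)
  span <- abs(out$icur_at_high - out$icur_at_low)
  out <- out[order(out$perspective, -span), ]
  rownames(out) <- NULL
  out
}

#' Build PSA sampling distributions from published ranges
#'
#' Families by parameter domain: beta for probabilities and utilities
#' (moments matched to the point value and a normal-approximation SD of
#' `(high - low) / 3.92`), lognormal for relative risks (median at the point
#' value, log-SD from the CI width), gamma for costs with a range. A
#' one-sided range uses the base value for the missing side (halving the
#' spread); a degenerate range (low = high = value) is a point mass, and an
#' infeasible beta moment match falls back to uniform over the range with a
#' warning. Parameters without ranges stay fixed at base case.
#'
#' @param params A validated `uc_parameters` object.
#' @return List of spec lists: `parameter`, `family`
#'   (`"beta"`, `"lognormal"`, `"gamma"`, `"uniform"`, `"fixed"`), `pars`.
#' @export
build_psa_specs <- function(params) {
  stopifnot(inherits(params, "uc_parameters"))
  bounds <- params$bounds
  specs <- lapply(seq_len(nrow(bounds)), function(i) {
    name <- bounds$parameter[i]
    value <- param_get(params, name)
    lo <- if (is.na(bounds$low[i])) value else bounds$low[i]
    hi <- if (is.na(bounds$high[i])) value else bounds$high[i]
    if (lo == hi) {
      return(list(parameter = name, family = "fixed", pars = list(value = value)))
    }
    sd <- (hi - lo) / 3.92
    group <- strsplit(name, ".", fixed = TRUE)[[1]][1]
    leaf <- strsplit(name, ".", fixed = TRUE)[[1]][2]
    is_rr <- group == "clinical" && grepl("^rr_", leaf)
    if (is_rr) {
      list(parameter = name, family = "lognormal",
           pars = list(meanlog = log(value), sdlog = (log(hi) - log(lo)) / 3.92))
    } else if (group == "costs") {
      list(parameter = name, family = "gamma",
           pars = list(shape = (value / sd)^2, rate = value / sd^2))
    } else {
      m <- value
      v <- sd^2
      if (m <= 0 || m >= 1 || v >= m * (1 - m)) {
        warning("infeasible beta moment match for ", name,
                "; falling back to uniform(", lo, ", ", hi, ")")
        list(parameter = name, family = "uniform", pars = list(min = lo, max = hi))
      } else {
        k <- m * (1 - m) / v - 1
        list(parameter = name, family = "beta",
             pars = list(shape1 = m * k, shape2 = (1 - m) * k))
      }
    }
  })
  specs
}

#' Sample one PSA parameter set
#'
#' Draws every spec independently and writes the values into a copy of the
#' base parameter set. Uses the current RNG state.
#'
#' @param params Base `uc_parameters`.
#' @param specs Result of [build_psa_specs()].
#' @return A `uc_parameters` object with sampled values.
#' @export
sample_psa_draw <- function(params, specs) {
  for (sp in specs) {
    value <- switch(sp$family,
      fixed = sp$pars$value,
      beta = stats::rbeta(1, sp$pars$shape1, sp$pars$shape2),
      lognormal = stats::rlnorm(1, sp$pars$meanlog, sp$pars$sdlog),
      gamma = stats::rgamma(1, shape = sp$pars$shape, rate = sp$pars$rate),
      uniform = stats::runif(1, sp$pars$min, sp$pars$max),
      stop("unknown family: ", sp$family)
    )
    params <- param_set(params, sp$parameter, value)
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Samples all uncertain parameters jointly-independently, reruns both arms
#' per draw, and summarises incremental results: ICUR as the ratio of mean
#' increments and as the mean of per-draw ratios, a percentile CI of the
#' per-draw ratios, and cost-effectiveness acceptability curves
#' `CEAC(lambda) = P(lambda * dQALY - dCost >= 0)` per perspective. Draws
#' failing parameter validation are redrawn (counted in `n_redraws`).
#' Reproducible given `seed`.
#'
#' @param params Base `uc_parameters`.
#' @param table A `uc_life_table`.
#' @param n_draws Number of retained draws (default 1000).
#' @param seed RNG seed.
#' @param wtp_grid Willingness-to-pay grid in EUR/QALY.
#' @return Object of class `uc_psa`: `draws` (per-draw increments, EUR),
#'   `summary` (per perspective: ratio-of-means and mean-of-ratios ICUR with
#'   percentile CI), `ceac` (`wtp`, `prob_payer`, `prob_social`), `seed`,
#'   `n_draws`, `n_redraws`.
#' @export
run_psa <- function(params, table, n_draws = 1000,
                    seed = params$settings$seed,
                    wtp_grid = seq(0, 150000, by = 1000)) {
  stopifnot(n_draws >= 1)
  specs <- build_psa_specs(params)
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, 3,
                  dimnames = list(NULL, c("delta_cost_payer_eur",
                                          "delta_cost_social_eur",
                                          "delta_qaly")))
  n_redraws <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      cand <- sample_psa_draw(params, specs)
      if (!length(validate_parameters(cand))) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 100 * n_draws) stop("PSA redraw limit exceeded")
    }
    cea <- run_cea(cand, table)$cea
    draws[i, ] <- c(cea$delta_cost_payer_eur, cea$delta_cost_social_eur,
                    cea$delta_qaly)
  }
  draws <- as.data.frame(draws)

  summarise <- function(dc) {
    r <- dc / draws$delta_qaly
    list(
      icur_ratio_of_means = mean(dc) / mean(draws$delta_qaly),
      icur_mean_of_ratios = mean(r),
      icur_ci = stats::quantile(r, c(0.025, 0.975), names = FALSE)
    )
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    prob_payer = vapply(wtp_grid, function(l) {
      mean(l * draws$delta_qaly - draws$delta_cost_payer_eur >= 0)
    }, numeric(1)),
    prob_social = vapply(wtp_grid, function(l) {
      mean(l * draws$delta_qaly - draws$delta_cost_social_eur >= 0)
    }, numeric(1))
  )
  structure(list(
    draws = draws,
    summary = list(payer = summarise(draws$delta_cost_payer_eur),
                   social = summarise(draws$delta_cost_social_eur)),
    ceac = ceac,
    seed = seed, n_draws = n_draws, n_redraws = n_redraws
  ), class = "uc_psa")
}

#' Willingness-to-pay at which the CEAC crosses a probability level
#'
#' @param psa A `uc_psa` object.
#' @param level Probability level (default 0.5).
#' @param perspective `"payer"` or `"social"`.
#' @return Smallest grid WTP with acceptability probability >= `level`
#'   (`NA` if never reached).
#' @export
ceac_crossing <- function(psa, level = 0.5,
                          perspective = c("payer", "social")) {
  perspective <- match.arg(perspective)
  p <- if (perspective == "payer") psa$ceac$prob_payer else psa$ceac$prob_social
  i <- which(p >= level)
  if (!length(i)) return(NA_real_)
  psa$ceac$wtp[i[1]]
}

#' Unlimited-treatment-duration scenario
#'
#' Reruns the full comparison with the biologic treatment cap removed:
#' dosing and biologic-arm transition probabilities persist while patients
#' remain in response or remission (treatment until loss of response or
#' death).
#'
#' @inheritParams run_owsa
#' @return As [run_cea()].
#' @export
run_scenario_unlimited <- function(params, table) {
  params$settings$treatment_cap_weeks <- Inf
  run_cea(params, table)
}

#' Write OWSA / PSA products to CSV
#'
#' Every file starts with a commented metadata line (`# seed=…`) so each
#' output references the run that produced it.
#'
#' @param owsa Result of [run_owsa()].
#' @param psa A `uc_psa` object.
#' @param path Output path.
#' @param seed Seed recorded in the metadata line.
#' @name sensitivity_io
NULL

#' @rdname sensitivity_io
#' @export
write_owsa_csv <- function(owsa, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# one-way sensitivity analysis; seed=%s", seed), con)
  utils::write.csv(owsa, con, row.names = FALSE)
  invisible(path)
}

#' @rdname sensitivity_io
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "uc_psa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# probabilistic sensitivity analysis; seed=%d; n_draws=%d; n_redraws=%d",
                     psa$seed, psa$n_draws, psa$n_redraws), con)
  utils::write.csv(psa$draws, con, row.names = FALSE)
  invisible(path)
}

#' @rdname sensitivity_io
#' @export
write_ceac_csv <- function(psa, path) {
  stopifnot(inherits(psa, "uc_psa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cost-effectiveness acceptability curve; seed=%d; n_draws=%d",
                     psa$seed, psa$n_draws), con)
  utils::write.csv(psa$ceac, con, row.names = FALSE)
  invisible(path)
}
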