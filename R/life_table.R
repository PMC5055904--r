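#' Construct and validate a life table
#'
#' A life table is the model's only mortality mechanism: a contiguous,
#' ascending set of integer ages with the annual death probability `qx` at
#' each age. Disease-specific excess mortality is deliberately absent
#' (ulcerative colitis does not shorten life expectancy), so one table serves
#' every health state.
#'
#' @param ages Integer ages, contiguous and ascending.
#' @param qx Annual death probabilities in `[0, 1]`, one per age.
#' @return A `data.frame` of class `uc_life_table` with columns `age`, `qx`.
#' @export
life_table <- function(ages, qx) {
  if (length(ages) != length(qx)) stop("'ages' and 'qx' must have equal length")
  if (length(ages) == 0) stop("life table must have at least one row")
  if (any(is.na(ages)) || any(ages != floor(ages))) {
    stop("'ages' must be integer years")
  }
  d <- diff(ages)
  if (any(d != 1)) {
    bad <- ages[which(d != 1)[1]] + 1
    stop("life table ages must be contiguous and ascending; missing age ", bad)
  }
  if (any(is.na(qx)) || any(qx < 0 | qx > 1)) {
    bad <- which(is.na(qx) | qx < 0 | qx > 1)[1]
    stop(sprintf("qx at age %d is outside [0, 1]", as.integer(ages[bad])))
  }
  structure(data.frame(age = as.integer(ages), qx = as.numeric(qx)),
            class = c("uc_life_table", "data.frame"))
}

#' Read a life table from CSV
#'
#' Expects a two-column CSV with header `age,qx`, ages in integer years and
#' `qx` as a decimal annual death probability.
#'
#' @param path CSV file path.
#' @return A `uc_life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("age", "qx"))) {
    stop("life table CSV must have header 'age,qx'; got: ",
         paste(names(df), collapse = ","))
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$age))) |
                 !is.finite(suppressWarnings(as.numeric(df$qx))))
  if (length(bad)) {
    stop("malformed life table row at line ", bad[1] + 1L, " of ", path)
  }
  life_table(as.numeric(df$age), as.numeric(df$qx))
}

#' @rdname read_life_table
#' @param table A `uc_life_table`.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "uc_life_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default parameters of the synthetic mortality curve
#'
#' Gompertz parameters calibrated so that the generated table's life
#' expectancy at birth is 77.0 years, the magnitude of the mid-2010s Polish
#' general population. The slope `b = 0.092`/year is a typical adult
#' log-hazard slope; `a` was solved for the life-expectancy target. The
#' generated table is a documented synthetic stand-in for a national
#' statistical-office life table, not a transcription of one.
#'
#' @return List with `gompertz_a`, `gompertz_b`, `max_age`.
#' @export
default_mortality_params <- function() {
  list(gompertz_a = 4.553585e-05, gompertz_b = 0.092, max_age = 110L)
}

#' Generate a synthetic Gompertz life table
#'
#' Annual death probability at age `x` is `1 - exp(-a * exp(b * x))`, clipped
#' to `[0, 1]`; deterministic given the parameters.
#'
#' @param gompertz_a Baseline hazard (1/year), positive.
#' @param gompertz_b Log-hazard slope (1/year), non-negative.
#' @param ages Integer age range of the table.
#' @return A `uc_life_table`.
#' @export
#' @examples
#' lt <- synth_life_table()
#' life_expectancy(lt) # ~77 years
synth_life_table <- function(gompertz_a = default_mortality_params()$gompertz_a,
                             gompertz_b = default_mortality_params()$gompertz_b,
                             ages = 0:default_mortality_params()$max_age) {
  stopifnot(gompertz_a > 0, gompertz_b >= 0)
  qx <- 1 - exp(-gompertz_a * exp(gompertz_b * ages))
  life_table(ages, pmin(pmax(qx, 0), 1))
}

#' Blend sex-specific life tables
#'
#' The model uses a unisex table by default; when separate female and male
#' tables are available they can be blended by the cohort's female fraction
#' (default 42.7%), weighting the annual death probabilities age by age.
#'
#' @param female,male `uc_life_table`s covering identical age ranges.
#' @param fraction_female Weight on the female table, in `[0, 1]`.
#' @return A `uc_life_table`.
#' @export
blend_life_tables <- function(female, male, fraction_female = 0.427) {
  stopifnot(inherits(female, "uc_life_table"), inherits(male, "uc_life_table"),
            fraction_female >= 0, fraction_female <= 1)
  if (!identical(female$age, male$age)) {
    stop("the two life tables must cover identical age ranges")
  }
  life_table(female$age,
             fraction_female * female$qx + (1 - fraction_female) * male$qx)
}

#' Expectation of life from a life table
#'
#' Complete expectation of life at `age`, computed as the curtate expectation
#' from the table plus a half-year; survival beyond the last tabulated age is
#' extrapolated geometrically at the final `qx`.
#'
#' @param table A `uc_life_table`.
#' @param age Integer starting age (default 0).
#' @return Expected further years of life.
#' @export
life_expectancy <- function(table, age = 0) {
  stopifnot(inherits(table, "uc_life_table"))
  if (age < table$age[1] || age > table$age[nrow(table)]) {
    stop("age outside the life table range")
  }
  qx <- table$qx[table$age >= age]
  S <- cumprod(1 - qx)
  tail_q <- qx[length(qx)]
  tail_sum <- if (tail_q > 0) S[length(S)] * (1 - tail_q) / tail_q else Inf
  sum(S) + tail_sum + 0.5
}

#' Per-cycle death probability from a life table
#'
#' Looks up the annual death probability at the completed age and rescales it
#' to the cycle length under a constant within-year hazard. The same value
#' applies to every alive health state: the model assumes no disease-specific
#' mortality.
#'
#' @param table A `uc_life_table`.
#' @param age_at_cycle_start Age in (possibly fractional) years.
#' @param cycle_length_weeks Cycle length in weeks.
#' @return Probability of death within the cycle.
#' @export
cycle_death_prob <- function(table, age_at_cycle_start, cycle_length_weeks) {
  stopifnot(inherits(table, "uc_life_table"),
            is.numeric(age_at_cycle_start), is.numeric(cycle_length_weeks),
            cycle_length_weeks > 0)
  a <- floor(age_at_cycle_start)
  i <- match(a, table$age)
  if (is.na(i)) {
    stop(sprintf(
      "age %.1f is outside the life table (ages %d-%d); extend the table past the model horizon",
      age_at_cycle_start, table$age[1], table$age[nrow(table)]
    ))
  }
  annual_prob_to_cycle(table$qx[i], cycle_length_weeks / 52)
}
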