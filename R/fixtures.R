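#' Run the base-case analysis end to end
#'
#' Thin driver: loads (or takes) parameters and a life table, runs both arms,
#' and writes the results table, both traces and a run manifest under
#' `out_dir`. This and the sensitivity drivers are the entry points used by
#' the numbered scripts in `analysis/`.
#'
#' @param params A `uc_parameters` object, or a path to a parameter YAML.
#' @param table A `uc_life_table`, or a path to a life-table CSV.
#' @param out_dir Output directory (created if missing). `NULL` skips
#'   writing.
#' @return The [run_cea()] result, invisibly when writing.
#' @export
run_basecase <- function(params, table, out_dir = NULL) {
  if (is.character(params)) params <- read_parameters(params)
  if (is.character(table)) table <- read_life_table(table)
  viol <- validate_parameters(params)
  if (length(viol)) {
    stop("invalid parameters:\n  - ", paste(viol, collapse = "\n  - "))
  }
  res <- run_cea(params, table)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_csv(res, file.path(out_dir, "basecase_results.csv"))
    write_trace_csv(res$trace_ada, file.path(out_dir, "trace_ada.csv"))
    write_trace_csv(res$trace_soc, file.path(out_dir, "trace_soc.csv"))
    write_manifest(params, file.path(out_dir, "manifest.json"),
                   outputs = c("basecase_results.csv", "trace_ada.csv",
                               "trace_soc.csv"))
    return(invisible(res))
  }
  res
}

#' Write a run manifest
#'
#' JSON record of the run: a hash of the full parameter set, the seed,
#' timestamp, package version and the files produced, so every output can be
#' traced to its configuration.
#'
#' @param params The `uc_parameters` used.
#' @param path Manifest path.
#' @param outputs Character vector of output file names.
#' @param extra Named list of extra fields (e.g. `n_draws`).
#' @export
write_manifest <- function(params, path, outputs = character(0),
                           extra = list()) {
  core <- params[c("cohort", "clinical", "utilities", "costs", "settings")]
  hash <- sum(as.integer(serialize(core, NULL, version = 2)[-(1:14)])) %% 2^31
  manifest <- c(list(
    config_hash = sprintf("%08x", hash),
    seed = params$settings$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("uccea")),
    outputs = outputs
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write the shipped fixtures
#'
#' Emits the inputs every analysis starts from: the synthetic life table
#' (`life_table_synthetic.csv`), the default parameter file
#' (`parameters_default.yaml`) transcribing the published clinical and cost
#' tables, and a short-horizon toy configuration
#' (`parameters_toy.yaml`, 16-week horizon, no discounting) whose two-cycle
#' expectation can be verified by hand. All outputs are deterministic.
#'
#' @param out_dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
write_fixture_files <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lt_path <- file.path(out_dir, "life_table_synthetic.csv")
  write_life_table(synth_life_table(), lt_path)

  par_path <- file.path(out_dir, "parameters_default.yaml")
  write_parameters(default_parameters(), par_path)

  toy <- default_parameters()
  toy$settings$horizon_years <- 16 / 52
  toy$settings$discount_rate_costs <- 0
  toy$settings$discount_rate_effects <- 0
  toy_path <- file.path(out_dir, "parameters_toy.yaml")
  write_parameters(toy, toy_path)

  files <- c(lt_path, par_path, toy_path)
  for (f in files) {
    if (!file.exists(f)) stop("fixture not written: ", f)
  }
  invisible(files)
}
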