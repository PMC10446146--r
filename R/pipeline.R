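# One-call pipeline stages mirroring the analysis workflow, each taking a
# configuration list (or YAML path), writing self-describing JSON/CSV
# artifacts, and returning its result invisibly. The thin command-line
# wrapper in inst/cli/nanorelease.R dispatches straight to run_pipeline().

#' Run one pipeline stage from a configuration
#'
#' Stages:
#' \describe{
#'   \item{`release`}{filter-sample CSV -> release-factor report
#'     (CSV + JSON). Config: `samples` (path), optional `n_units`,
#'     `area_per_unit_m2`, `rounding` ("table1" or "raw").}
#'   \item{`scenario`}{YAML scenario -> exposure report (JSON + profile
#'     CSV). Config: `scenario` (path) or inline `room`/`purifiers`/`oels`.}
#'   \item{`infer`}{series CSV -> emission bound (JSON). Config: `series`
#'     (path), `volume_m3`, optional `exclusions` (path), `window_s`,
#'     `k_sigma`.}
#'   \item{`simulate`}{box-model profile -> CSV. Config: `volume_m3`,
#'     `flow_m3h`, `source_ngh`, optional `deposition_per_h`,
#'     `outdoor_conc`, `penetration`, `init_conc`, `duration_h`.}
#'   \item{`synth`}{synthetic chamber series -> CSV + truth JSON. Config:
#'     [sim_chamber_series()] arguments; `seed` required.}
#' }
#'
#' @param command One of `"release"`, `"scenario"`, `"infer"`,
#'   `"simulate"`, `"synth"`.
#' @param config Named list, or path to a YAML file holding one.
#' @param out Output stem; artifacts are written as `<out>.json` /
#'   `<out>.csv` (omit to skip writing).
#' @param seed Integer seed for stochastic stages (overrides the config).
#' @return The stage result, invisibly.
#' @export
run_pipeline <- function(command = c(
                           "release", "scenario", "infer",
                           "simulate", "synth"
                         ),
                         config = list(), out = NULL, seed = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- seed
  result <- switch(command,
    release = .stage_release(config, out),
    scenario = .stage_scenario(config, out),
    infer = .stage_infer(config, out),
    simulate = .stage_simulate(config, out),
    synth = .stage_synth(config, out)
  )
  invisible(result)
}

.write_json_report <- function(payload, config, out) {
  if (is.null(out)) {
    return(invisible(NULL))
  }
  payload$config <- config
  payload$package_version <- as.character(utils::packageVersion("nanorelease"))
  jsonlite::write_json(
    payload, paste0(out, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
}

.stage_release <- function(config, out) {
  samples <- if (!is.null(config$samples)) {
    read_filter_samples_csv(config$samples)
  } else {
    abort("release stage needs `samples` (CSV path) in the config.")
  }
  surface <- surface_spec(
    n_units = config$n_units %||% 3,
    area_per_unit_m2 = config$area_per_unit_m2 %||% 0.009
  )
  report <- release_report(samples, surface,
    rounding = config$rounding %||% "table1"
  )
  if (!is.null(out)) {
    readr::write_csv(report, paste0(out, ".csv"))
    .write_json_report(
      list(report = report),
      config[setdiff(names(config), "samples_data")], out
    )
  }
  report
}

.stage_scenario <- function(config, out) {
  parsed <- if (!is.null(config$scenario) && is.character(config$scenario)) {
    read_scenario_config(config$scenario)
  } else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(config, tmp)
    read_scenario_config(tmp)
  }
  report <- run_scenario(parsed$scenario, parsed$oels)
  if (!is.null(out)) {
    readr::write_csv(as_tibble(report$profile), paste0(out, "_profile.csv"))
    .write_json_report(
      list(
        source_rate_ngh = report$source_rate_ngh,
        steady_state_ngm3 = report$steady_state_ngm3,
        loss_rate_per_h = report$loss_rate_per_h,
        time_to_95pct_h = report$time_to_95pct_h,
        risk = report$risk
      ),
      parsed$raw, out
    )
  }
  report
}

.stage_infer <- function(config, out) {
  if (is.null(config$series) || is.null(config$volume_m3)) {
    abort("infer stage needs `series` (CSV path) and `volume_m3`.")
  }
  series <- read_series_csv(config$series,
    metric = config$metric %||% "number"
  )
  intervals <- if (!is.null(config$exclusions)) {
    read_exclusions_csv(config$exclusions)
  } else {
    NULL
  }
  bound <- infer_emission(
    series,
    volume_m3 = config$volume_m3, intervals = intervals,
    window_s = config$window_s %||% 900,
    k_sigma = config$k_sigma %||% 1
  )
  .write_json_report(list(emission = bound), config, out)
  bound
}

.stage_simulate <- function(config, out) {
  if (is.null(config$volume_m3)) abort("simulate stage needs `volume_m3`.")
  comp <- compartment(
    volume_m3 = config$volume_m3,
    flow_m3h = config$flow_m3h %||% 0,
    penetration = config$penetration %||% 1,
    deposition_per_h = config$deposition_per_h %||% 0,
    outdoor_conc = config$outdoor_conc %||% 0
  )
  sinks <- source_sink_set(rate = config$source_ngh %||% 0)
  duration <- config$duration_h %||% 10
  profile <- solve_profile(
    comp, sinks,
    init_conc = config$init_conc %||% 0,
    times_h = seq(0, duration, length.out = config$n_times %||% 201)
  )
  if (!is.null(out)) {
    readr::write_csv(as_tibble(profile), paste0(out, ".csv"))
    .write_json_report(list(glance = glance(profile)), config, out)
  }
  profile
}

.stage_synth <- function(config, out) {
  if (is.null(config$seed)) abort("synth stage needs a `seed`.")
  args <- config[intersect(names(config), names(formals(sim_chamber_series)))]
  series <- do.call(sim_chamber_series, args)
  if (!is.null(out)) {
    write_series_csv(series, paste0(out, ".csv"))
    excl <- attr(series, "exclusions")
    if (nrow(excl)) readr::write_csv(excl, paste0(out, "_exclusions.csv"))
    .write_json_report(list(truth = attr(series, "truth")), config, out)
  }
  series
}
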