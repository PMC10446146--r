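# Readers and writers for the package's plain-text formats: concentration
# series CSV (timestamp,concentration; timestamps either elapsed seconds or
# ISO-8601), filter-sample CSV, exclusion-interval CSV, and the YAML
# scenario configuration. Validation reports offending line numbers;
# reports embed the resolved configuration so outputs are self-describing.

#' Read a concentration time series from CSV
#'
#' Expects columns `timestamp` and `concentration`. Timestamps may be
#' elapsed seconds or ISO-8601 datetimes; the format is auto-detected and
#' ISO-8601 stamps are converted to seconds elapsed since the first sample.
#'
#' @param path CSV file path.
#' @param metric `"number"` (1/cm^3) or `"mass"` (ng/m^3).
#' @param instrument Optional instrument label attached to the series.
#' @return A [conc_series()].
#' @export
read_series_csv <- function(path, metric = c("number", "mass"),
                            instrument = NA_character_) {
  metric <- match.arg(metric)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  need <- c("timestamp", "concentration")
  if (!all(need %in% names(df))) {
    abort(paste0(
      "series CSV must have columns `timestamp` and `concentration`; ",
      "found: ", paste(names(df), collapse = ", "), "."
    ))
  }
  if (nrow(df) < 2) abort("series CSV needs at least 2 rows.")
  conc <- suppressWarnings(as.numeric(df$concentration))
  bad <- which(is.na(conc))
  if (length(bad)) {
    abort(paste0(
      "non-numeric concentration at data line(s) ",
      paste(head(bad, 5), collapse = ", "), " of ", path, "."
    ))
  }
  neg <- which(conc < 0)
  if (length(neg)) {
    abort(paste0(
      "negative concentration at data line(s) ",
      paste(head(neg, 5), collapse = ", "), " of ", path, "."
    ))
  }
  elapsed <- suppressWarnings(as.numeric(df$timestamp))
  if (!any(is.na(elapsed))) {
    time_s <- elapsed
  } else {
    stamps <- as.POSIXct(df$timestamp,
      tz = "UTC",
      tryFormats = c(
        "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
        "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"
      )
    )
    bad <- which(is.na(stamps))
    if (length(bad)) {
      abort(paste0(
        "unparseable timestamp at data line(s) ",
        paste(head(bad, 5), collapse = ", "), " of ", path, "."
      ))
    }
    time_s <- as.numeric(difftime(stamps, stamps[1], units = "secs"))
  }
  nonmono <- which(diff(time_s) <= 0)
  if (length(nonmono)) {
    abort(paste0(
      "timestamps not strictly increasing at data line(s) ",
      paste(head(nonmono + 1, 5), collapse = ", "), " of ", path, "."
    ))
  }
  conc_series(time_s, conc, metric = metric, instrument = instrument)
}

#' @rdname read_series_csv
#' @param series A [conc_series()] to write.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "conc_series"))
  readr::write_csv(
    tibble(timestamp = series$time_s, concentration = series$conc),
    path
  )
  invisible(path)
}

#' Read exclusion intervals from CSV
#'
#' Expects columns `start` and `end`, in seconds.
#'
#' @param path CSV file path.
#' @return An [exclusion_intervals()] tibble.
#' @export
read_exclusions_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path,
    col_types = readr::cols(
      start = readr::col_double(), end = readr::col_double()
    ),
    progress = FALSE
  )
  exclusion_intervals(df$start, df$end)
}

#' Read filter samples from CSV
#'
#' Expects columns `label, ti_mass_ng, censored, loq_ng, volume_m3,
#' duration_h`; `ti_mass_ng` may be blank for censored rows.
#'
#' @param path CSV file path.
#' @return A [filter_samples()] table.
#' @export
read_filter_samples_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path,
    col_types = readr::cols(
      label = readr::col_character(),
      ti_mass_ng = readr::col_double(),
      censored = readr::col_logical(),
      loq_ng = readr::col_double(),
      volume_m3 = readr::col_double(),
      duration_h = readr::col_double()
    ),
    progress = FALSE
  )
  filter_samples(
    label = df$label, ti_mass_ng = df$ti_mass_ng, censored = df$censored,
    loq_ng = df$loq_ng, volume_m3 = df$volume_m3, duration_h = df$duration_h
  )
}

#' Read a room-scenario configuration from YAML
#'
#' Schema (keys in parentheses optional):
#' ```
#' room: {volume_m3, ach_per_h, (deposition_per_h), (outdoor_conc_ngm3),
#'        (penetration)}
#' purifiers:
#'   - {flow_m3h, release_factor_ngm2m3, (n_units), (area_per_unit_m2),
#'      (filtration_efficiency)}
#' (oels:)
#'   - {name, value_ugm3, (averaging), (divisor)}
#' (duration_h), (init_conc_ngm3)
#' ```
#'
#' @param path YAML (or JSON) file path.
#' @return A list with `scenario` (a [room_scenario()]) and `oels`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$room) || is.null(cfg$room$volume_m3) ||
    is.null(cfg$room$ach_per_h)) {
    abort("scenario config needs room: {volume_m3, ach_per_h}.")
  }
  purifiers <- purrr::map(cfg$purifiers %||% list(), function(p) {
    if (is.null(p$flow_m3h)) abort("each purifier needs `flow_m3h`.")
    purifier(
      flow_m3h = p$flow_m3h,
      surface = surface_spec(
        n_units = p$n_units %||% 3,
        area_per_unit_m2 = p$area_per_unit_m2 %||% 0.009
      ),
      release_factor = p$release_factor_ngm2m3 %||% 0,
      filtration_efficiency = p$filtration_efficiency %||% 0
    )
  })
  oels <- purrr::map(cfg$oels %||% list(), function(o) {
    if (is.null(o$name) || is.null(o$value_ugm3)) {
      abort("each oel needs `name` and `value_ugm3`.")
    }
    oel_reference(
      name = o$name, value_ugm3 = o$value_ugm3,
      averaging = o$averaging %||% "8h_occupational",
      divisor = o$divisor %||% 3
    )
  })
  scenario <- room_scenario(
    room_volume_m3 = cfg$room$volume_m3,
    ach_per_h = cfg$room$ach_per_h,
    purifiers = purifiers,
    deposition_per_h = cfg$room$deposition_per_h %||% 0,
    outdoor_conc = cfg$room$outdoor_conc_ngm3 %||% 0,
    penetration = cfg$room$penetration %||% 1,
    duration_h = cfg$duration_h %||% 10,
    init_conc = cfg$init_conc_ngm3 %||% 0
  )
  list(scenario = scenario, oels = oels, raw = cfg)
}
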