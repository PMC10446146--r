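# Filter-based release quantification. Gravimetric Ti on a quartz filter,
# possibly censored at the assay's limit of quantification (LOQ), is turned
# into (upper bounds on) Ti and TiO2 concentration per ventilated volume,
# a TiO2 emission rate, and a generalized release factor per photoactive
# area and ventilated volume. Censored samples propagate as "<" bounds.
#
# Reported-table rounding convention ("table1" mode): Ti concentration is
# rounded to 1 significant figure, the TiO2 concentration is the rounded Ti
# times the molar-mass factor, itself rounded to 1 significant figure; the
# emission rate is the *raw* TiO2 concentration times the empirical mean
# flow, printed at 2 significant figures; the release factor is the printed
# TiO2 concentration divided by the photoactive area, printed at 3
# significant figures. Raw unrounded values are always carried alongside.

#' Build a table of filter samples
#'
#' One row per gravimetric filter sample: the Ti mass found (or the LOQ it
#' fell below), the sampled air volume, and the sampling duration. A
#' censored sample is one whose Ti mass was below the assay LOQ; its mass
#' is unknown and only the LOQ-based upper bound is usable.
#'
#' @param label Sample labels.
#' @param ti_mass_ng Measured Ti mass in ng (`NA` for censored samples).
#' @param censored Logical: was the result below the LOQ?
#' @param loq_ng Limit of quantification in ng (> 0).
#' @param volume_m3 Sampled air volume in m^3 (> 0).
#' @param duration_h Sampling duration in h (> 0).
#' @return A tibble of class `filter_samples`.
#' @examples
#' filter_samples(
#'   label = c("Test 2A", "Test 2B"),
#'   censored = TRUE, loq_ng = 1,
#'   volume_m3 = c(303.7, 229.6), duration_h = c(96, 72)
#' )
#' @export
filter_samples <- function(label, ti_mass_ng = NA_real_, censored = FALSE,
                           loq_ng = 1, volume_m3, duration_h) {
  out <- tibble(
    label = as.character(label),
    ti_mass_ng = as.numeric(ti_mass_ng),
    censored = as.logical(censored),
    loq_ng = as.numeric(loq_ng),
    volume_m3 = as.numeric(volume_m3),
    duration_h = as.numeric(duration_h)
  )
  if (any(out$loq_ng <= 0)) abort("`loq_ng` must be > 0.")
  if (any(out$volume_m3 <= 0)) abort("`volume_m3` must be > 0.")
  if (any(out$duration_h <= 0)) abort("`duration_h` must be > 0.")
  bad <- !out$censored & (is.na(out$ti_mass_ng) | out$ti_mass_ng < 0)
  if (any(bad)) {
    abort("uncensored samples need a non-negative `ti_mass_ng`.")
  }
  structure(out, class = c("filter_samples", class(tibble())))
}

#' Photoactive surface specification
#'
#' @param n_units Number of coated units (honeycombs) sampled (>= 1).
#' @param area_per_unit_m2 Photoactive area per unit, m^2. Default 0.009
#'   (90 cm^2, the low end of the manufactured 90-100 cm^2 range, which is
#'   the value consistent with the reported release factors).
#' @return A list of class `surface_spec` with the derived `total_area_m2`.
#' @examples
#' surface_spec() # three 90 cm2 honeycombs: 0.027 m2
#' @export
surface_spec <- function(n_units = 3, area_per_unit_m2 = 0.009) {
  stopifnot(n_units >= 1, area_per_unit_m2 > 0)
  structure(
    list(
      n_units = n_units,
      area_per_unit_m2 = area_per_unit_m2,
      total_area_m2 = n_units * area_per_unit_m2
    ),
    class = "surface_spec"
  )
}

#' Ti concentration (or its LOQ upper bound) per ventilated volume
#'
#' For a censored sample the collected Ti mass is below the LOQ, so
#' `loq / volume` is an upper bound on the concentration; for an uncensored
#' sample `mass / volume` is the estimate itself.
#'
#' @param samples A [filter_samples()] table.
#' @return The table with `conc_ti` (ng/m^3) and `is_upper_bound` appended.
#' @export
bound_ti_concentration <- function(samples) {
  stopifnot(inherits(samples, "filter_samples"))
  samples |>
    mutate(
      conc_ti = ifelse(.data$censored,
        .data$loq_ng / .data$volume_m3,
        .data$ti_mass_ng / .data$volume_m3
      ),
      is_upper_bound = .data$censored
    )
}

#' Release factors from filter samples
#'
#' The full quantification chain: Ti concentration (or bound) per
#' ventilated volume, TiO2 equivalent via the molar-mass factor, TiO2
#' emission rate via the empirical mean flow (`volume / duration`, not the
#' nominal pump setting), and the generalized release factor per
#' photoactive area and ventilated volume. Raw values and reported-table
#' rounded values (see the package vignette for the rounding chain) are
#' both returned; every quantity derived from a censored sample is an upper
#' bound.
#'
#' @param samples A [filter_samples()] table.
#' @param surface A [surface_spec()].
#' @return A tibble of class `release_factors`: per sample, `conc_ti`,
#'   `conc_tio2` (ng/m^3), `rate_tio2` (ng/h), `rf_tio2` (ng/(m^2 m^3)),
#'   `mean_flow_m3h`, `is_upper_bound`, plus `printed_*` variants rounded
#'   by the reporting convention.
#' @examples
#' filter_samples("Test 2A",
#'   censored = TRUE, loq_ng = 1,
#'   volume_m3 = 303.7, duration_h = 96
#' ) |> release_factors(surface_spec())
#' @export
release_factors <- function(samples, surface = surface_spec()) {
  stopifnot(inherits(surface, "surface_spec"))
  fac <- material_constants()$ti_to_tio2_factor
  out <- bound_ti_concentration(samples) |>
    mutate(
      mean_flow_m3h = .data$volume_m3 / .data$duration_h,
      conc_tio2 = .data$conc_ti * fac,
      rate_tio2 = .data$conc_tio2 * .data$mean_flow_m3h,
      rf_tio2 = .data$conc_tio2 / surface$total_area_m2,
      printed_conc_ti = round_sig(.data$conc_ti, 1),
      printed_conc_tio2 = round_sig(.data$printed_conc_ti * fac, 1),
      printed_rate_tio2 = round_sig(.data$rate_tio2, 2),
      printed_rf_tio2 = round_sig(
        .data$printed_conc_tio2 / surface$total_area_m2, 3
      )
    )
  structure(
    out,
    surface = surface,
    class = c("release_factors", class(tibble()))
  )
}

#' Reported-style release table
#'
#' One row per sample with the six reporting columns (sampling time,
#' sampled volume, Ti and TiO2 concentrations, TiO2 emission rate and
#' release factor), either raw or under the reported rounding convention,
#' with `"<"` prefixes marking LOQ-censored upper bounds in the formatted
#' columns.
#'
#' @inheritParams release_factors
#' @param rounding `"table1"` (reported rounding chain, default) or
#'   `"raw"`.
#' @return A tibble with numeric columns and `"<"`-prefixed character
#'   display columns (`ti_display`, `tio2_display`, `rate_display`,
#'   `rf_display`).
#' @export
release_report <- function(samples, surface = surface_spec(),
                           rounding = c("table1", "raw")) {
  rounding <- match.arg(rounding)
  if (nrow(samples) < 1) abort("need at least one filter sample.")
  rf <- release_factors(samples, surface)
  use_printed <- rounding == "table1"
  choose <- function(raw, printed) if (use_printed) printed else raw
  disp <- function(x, bound) {
    paste0(ifelse(bound, "<", ""), format(x, scientific = TRUE, digits = 3))
  }
  rf |>
    mutate(
      conc_ti_out = choose(.data$conc_ti, .data$printed_conc_ti),
      conc_tio2_out = choose(.data$conc_tio2, .data$printed_conc_tio2),
      rate_tio2_out = choose(.data$rate_tio2, .data$printed_rate_tio2),
      rf_tio2_out = choose(.data$rf_tio2, .data$printed_rf_tio2),
      ti_display = disp(.data$conc_ti_out, .data$is_upper_bound),
      tio2_display = disp(.data$conc_tio2_out, .data$is_upper_bound),
      rate_display = disp(.data$rate_tio2_out, .data$is_upper_bound),
      rf_display = disp(.data$rf_tio2_out, .data$is_upper_bound)
    ) |>
    dplyr::select(
      "label", "duration_h", "volume_m3",
      conc_ti = "conc_ti_out", conc_tio2 = "conc_tio2_out",
      rate_tio2 = "rate_tio2_out", rf_tio2 = "rf_tio2_out",
      "is_upper_bound",
      "ti_display", "tio2_display", "rate_display", "rf_display"
    )
}

#' @rdname release_factors
#' @param x A `release_factors` table.
#' @param ... Unused.
#' @method tidy release_factors
#' @export
tidy.release_factors <- function(x, ...) {
  as_tibble(x)[, c(
    "label", "conc_ti", "conc_tio2", "rate_tio2", "rf_tio2",
    "mean_flow_m3h", "is_upper_bound"
  )]
}
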