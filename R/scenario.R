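# Room exposure scenarios: photocatalytic purifiers recirculating room air
# emit TiO2 at their surfaces' release factor; the room is a single fully
# mixed compartment ventilated at a fixed air-change rate. Predicted
# concentrations are compared against proposed occupational exposure limits
# (OELs) as risk-characterization ratios.

#' Define an air purifier as a source (and optional sink)
#'
#' A purifier recirculating `flow` m^3/h across a photoactive surface emits
#' `release_factor * total_area * flow` ng/h. If its filter removes
#' particles (`filtration_efficiency > 0`) it also acts as a clean-air
#' sink with equivalent flow `efficiency * flow`.
#'
#' @param flow_m3h Recirculation flow, m^3/h (>= 0).
#' @param surface A [surface_spec()]; default three 90 cm^2 honeycombs.
#' @param release_factor TiO2 release factor, ng/(m^2 m^3) (>= 0).
#' @param filtration_efficiency Single-pass particle removal fraction in
#'   `[0, 1]`; default 0 (photocatalytic honeycombs do not appreciably
#'   filter nanoparticles).
#' @return A list of class `purifier`.
#' @examples
#' purifier(flow_m3h = 10, release_factor = 0.185)
#' @export
purifier <- function(flow_m3h, surface = surface_spec(),
                     release_factor = 0, filtration_efficiency = 0) {
  stopifnot(
    flow_m3h >= 0, inherits(surface, "surface_spec"),
    release_factor >= 0,
    filtration_efficiency >= 0, filtration_efficiency <= 1
  )
  structure(
    list(
      flow_m3h = flow_m3h, surface = surface,
      release_factor = release_factor,
      filtration_efficiency = filtration_efficiency
    ),
    class = "purifier"
  )
}

#' Define a room exposure scenario
#'
#' @param room_volume_m3 Room volume, m^3 (> 0).
#' @param ach_per_h General-ventilation air-change rate, 1/h (>= 0).
#' @param purifiers List of [purifier()] objects (may be empty).
#' @param deposition_per_h Surface-deposition loss rate, 1/h (default 0).
#' @param outdoor_conc Supply-air TiO2 concentration, ng/m^3 (default 0).
#' @param penetration Supply-air penetration fraction (default 1).
#' @param duration_h Simulated duration, h (> 0; default 10).
#' @param init_conc Initial room concentration, ng/m^3 (default 0).
#' @return A list of class `room_scenario`.
#' @examples
#' # 20 m3 room at 0.5 1/h with two purifiers at 10 m3/h each
#' room_scenario(20, 0.5, purifiers = rep(
#'   list(purifier(10, release_factor = 0.185)), 2
#' ))
#' @export
room_scenario <- function(room_volume_m3, ach_per_h, purifiers = list(),
                          deposition_per_h = 0, outdoor_conc = 0,
                          penetration = 1, duration_h = 10, init_conc = 0) {
  stopifnot(
    room_volume_m3 > 0, ach_per_h >= 0, duration_h > 0, init_conc >= 0,
    all(vapply(purifiers, inherits, logical(1), "purifier"))
  )
  structure(
    list(
      room_volume_m3 = room_volume_m3, ach_per_h = ach_per_h,
      purifiers = purifiers, deposition_per_h = deposition_per_h,
      outdoor_conc = outdoor_conc, penetration = penetration,
      duration_h = duration_h, init_conc = init_conc
    ),
    class = "room_scenario"
  )
}

#' Reference exposure limit
#'
#' Proposed OELs for nanosized TiO2 span 0.8-5000 ug/m^3 as 8-h
#' time-weighted averages. For continuous 24-h population exposure the
#' limit is conventionally divided by 3.
#'
#' @param name Label for the limit.
#' @param value_ugm3 Limit value, ug/m^3 (> 0).
#' @param averaging `"8h_occupational"` or `"24h_population"`.
#' @param divisor Population adjustment divisor applied when
#'   `averaging = "24h_population"` (default 3).
#' @return A list of class `oel_reference`.
#' @examples
#' oel_reference("proposed low", 0.8)
#' @export
oel_reference <- function(name, value_ugm3,
                          averaging = c("8h_occupational", "24h_population"),
                          divisor = 3) {
  averaging <- match.arg(averaging)
  stopifnot(value_ugm3 > 0, divisor >= 1)
  structure(
    list(
      name = name, value_ugm3 = value_ugm3, averaging = averaging,
      divisor = divisor
    ),
    class = "oel_reference"
  )
}

#' Combined source rate of a set of purifiers
#'
#' The release factor normalises emitted mass by photoactive area and
#' ventilated air volume, so the room source rate is the combined coated
#' inventory `sum(release_factor * total_area)` exposed to the combined
#' recirculated airflow of the emitting units:
#' `(sum_i rf_i * A_i) * (sum over emitting units of Q_j)` ng/h. For a
#' single purifier this is the familiar `rf * A * Q`; for several
#' identical units sharing the same room air it matches the convention of
#' scaling one unit's release factor by the total photoactive area and
#' total volume flow. Units that release nothing (rf = 0) move air but
#' contribute neither inventory nor emission-coupled airflow.
#'
#' @param purifiers List of [purifier()] objects.
#' @return Source rate, ng/h.
#' @examples
#' # two units, three 90 cm2 honeycombs each, 10 m3/h each: ~0.20 ng/h
#' scenario_source_rate(rep(list(purifier(10, release_factor = 0.185)), 2))
#' @export
scenario_source_rate <- function(purifiers) {
  stopifnot(all(vapply(purifiers, inherits, logical(1), "purifier")))
  if (!length(purifiers)) {
    return(0)
  }
  inv_each <- vapply(
    purifiers,
    function(p) p$release_factor * p$surface$total_area_m2,
    numeric(1)
  )
  flows <- vapply(purifiers, function(p) p$flow_m3h, numeric(1))
  sum(inv_each) * sum(flows[inv_each > 0])
}

#' Risk-characterization ratio against an exposure limit
#'
#' Predicted concentration divided by the (population-adjusted) limit,
#' after converting ng/m^3 to ug/m^3. Ratios below 1 indicate adequately
#' controlled risk.
#'
#' @param conc_ngm3 Predicted concentration, ng/m^3 (>= 0).
#' @param oel An [oel_reference()].
#' @return Dimensionless ratio.
#' @examples
#' risk_ratio(0.02, oel_reference("proposed low", 0.8))
#' @export
risk_ratio <- function(conc_ngm3, oel) {
  stopifnot(inherits(oel, "oel_reference"), all(conc_ngm3 >= 0))
  limit_ngm3 <- oel$value_ugm3 * 1e3 /
    if (oel$averaging == "24h_population") oel$divisor else 1
  conc_ngm3 / limit_ngm3
}

#' Run a room exposure scenario
#'
#' Builds the equivalent well-mixed compartment (ventilation flow
#' `ach * volume`; each purifier contributes a source
#' `rf * area * flow` and, if filtering, a sink `efficiency * flow`),
#' solves the transient profile, and characterizes risk against any
#' supplied exposure limits. The time to reach 95% of steady state is
#' `ln(20) / k_total`.
#'
#' @param scenario A [room_scenario()].
#' @param oels Optional list of [oel_reference()] objects.
#' @param n_times Number of output grid points (default 201).
#' @return An `exposure_report`: list with `source_rate_ngh`,
#'   `steady_state_ngm3`, `loss_rate_per_h`, `time_to_95pct_h`, `profile`
#'   (a [solve_profile()] tibble) and `risk` (tibble of OEL ratios).
#' @examples
#' scn <- room_scenario(20, 0.5,
#'   purifiers = rep(list(purifier(10, release_factor = 0.185)), 2)
#' )
#' run_scenario(scn)$steady_state_ngm3
#' @export
run_scenario <- function(scenario, oels = list(), n_times = 201) {
  stopifnot(inherits(scenario, "room_scenario"))
  if (inherits(oels, "oel_reference")) oels <- list(oels)
  stopifnot(all(vapply(oels, inherits, logical(1), "oel_reference")))
  g <- scenario_source_rate(scenario$purifiers)
  sink_flows <- vapply(
    scenario$purifiers,
    function(p) p$filtration_efficiency * p$flow_m3h, numeric(1)
  )
  comp <- compartment(
    volume_m3 = scenario$room_volume_m3,
    flow_m3h = scenario$ach_per_h * scenario$room_volume_m3,
    penetration = scenario$penetration,
    deposition_per_h = scenario$deposition_per_h,
    outdoor_conc = scenario$outdoor_conc
  )
  sinks <- source_sink_set(rate = g, sink_flows_m3h = sink_flows)
  k <- total_loss_rate(comp, sinks)
  if (k <= 0 && g > 0) {
    abort(paste0(
      "No steady state: the scenario has a source but no removal ",
      "pathway (ach, deposition and filtration are all zero)."
    ))
  }
  profile <- solve_profile(
    comp, sinks,
    init_conc = scenario$init_conc,
    times_h = seq(0, scenario$duration_h, length.out = n_times)
  )
  c_ss <- attr(profile, "steady_state")
  risk <- if (length(oels)) {
    tibble(
      oel = vapply(oels, function(o) o$name, character(1)),
      limit_ugm3 = vapply(oels, function(o) o$value_ugm3, numeric(1)),
      averaging = vapply(oels, function(o) o$averaging, character(1)),
      ratio = vapply(oels, function(o) risk_ratio(c_ss, o), numeric(1))
    )
  } else {
    tibble(
      oel = character(0), limit_ugm3 = numeric(0),
      averaging = character(0), ratio = numeric(0)
    )
  }
  structure(
    list(
      source_rate_ngh = g,
      steady_state_ngm3 = c_ss,
      loss_rate_per_h = k,
      time_to_95pct_h = if (k > 0) log(20) / k else NA_real_,
      profile = profile,
      risk = risk,
      scenario = scenario
    ),
    class = "exposure_report"
  )
}

#' @rdname run_scenario
#' @param x,object An `exposure_report`.
#' @param ... Unused.
#' @method glance exposure_report
#' @export
glance.exposure_report <- function(x, ...) {
  tibble(
    source_rate_ngh = x$source_rate_ngh,
    steady_state_ngm3 = x$steady_state_ngm3,
    loss_rate_per_h = x$loss_rate_per_h,
    time_to_95pct_h = x$time_to_95pct_h,
    final_conc_ngm3 = x$profile$conc[nrow(x$profile)],
    max_risk_ratio = if (nrow(x$risk)) max(x$risk$ratio) else NA_real_
  )
}

#' @rdname run_scenario
#' @method tidy exposure_report
#' @export
tidy.exposure_report <- function(x, ...) {
  x$risk
}

#' @rdname run_scenario
#' @method autoplot exposure_report
#' @export
autoplot.exposure_report <- function(object, ...) {
  autoplot(object$profile) +
    labs(
      y = "room TiO2 concentration (ng/m³)",
      title = sprintf(
        "steady state %.3g ng/m³, 95%% reached at %.2g h",
        object$steady_state_ngm3, object$time_to_95pct_h
      )
    )
}

#' @export
print.exposure_report <- function(x, ...) {
  cat("<exposure_report>\n")
  cat("  source rate:", format(x$source_rate_ngh), "ng/h\n")
  cat("  steady state:", format(x$steady_state_ngm3), "ng/m3\n")
  cat("  loss rate:", format(x$loss_rate_per_h), "1/h\n")
  cat("  time to 95%:", format(x$time_to_95pct_h), "h\n")
  if (nrow(x$risk)) {
    cat("  risk ratios:\n")
    for (i in seq_len(nrow(x$risk))) {
      cat(
        "   ", x$risk$oel[i], ":",
        format(x$risk$ratio[i], digits = 3), "\n"
      )
    }
  }
  invisible(x)
}
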