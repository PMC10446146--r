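# Well-mixed single-compartment mass balance:
#   V dC/dt = G + P * Q * C_out - (Q + lambda_dep * V + sum(sink flows)) * C
# Inflow enters at penetration P, outflow leaves at the ventilation flow Q,
# deposition removes at first order lambda_dep, and each extra sink (e.g. a
# purifier's clean-air delivery eta * Q_p) removes at its equivalent flow.
# With constant coefficients the solution is an exponential relaxation to the
# steady state; an adaptive ODE integration is kept alongside as an
# independent numerical route.

#' Define a well-mixed compartment
#'
#' @param volume_m3 Compartment volume, m^3 (> 0).
#' @param flow_m3h Ventilation (supply/exhaust) volume flow, m^3/h (>= 0).
#' @param penetration Fraction of supply-air particles that survives entry,
#'   in `[0, 1]`.
#' @param deposition_per_h First-order surface-deposition loss rate, 1/h
#'   (>= 0).
#' @param outdoor_conc Supply/outdoor concentration in the state unit
#'   (constant, >= 0).
#' @return An object of class `compartment`.
#' @examples
#' compartment(volume_m3 = 20, flow_m3h = 10)
#' @export
compartment <- function(volume_m3, flow_m3h = 0, penetration = 1,
                        deposition_per_h = 0, outdoor_conc = 0) {
  stopifnot(
    is.numeric(volume_m3), length(volume_m3) == 1, volume_m3 > 0,
    flow_m3h >= 0, penetration >= 0, penetration <= 1,
    deposition_per_h >= 0, outdoor_conc >= 0
  )
  structure(
    list(
      volume_m3 = volume_m3, flow_m3h = flow_m3h,
      penetration = penetration, deposition_per_h = deposition_per_h,
      outdoor_conc = outdoor_conc
    ),
    class = "compartment"
  )
}

#' Define the sources and extra first-order sinks acting on a compartment
#'
#' @param rate Constant source rate, state-quantity per hour (>= 0). For a
#'   mass state this is ng/h; for a number state, particles/h.
#' @param sink_flows_m3h Numeric vector of equivalent clean-air flows, m^3/h,
#'   one per extra sink (e.g. `efficiency * purifier_flow`); may be empty.
#' @return An object of class `source_sink_set`.
#' @export
source_sink_set <- function(rate = 0, sink_flows_m3h = numeric(0)) {
  stopifnot(rate >= 0, all(sink_flows_m3h >= 0))
  structure(
    list(rate = rate, sink_flows_m3h = as.numeric(sink_flows_m3h)),
    class = "source_sink_set"
  )
}

#' Total first-order loss rate of a compartment
#'
#' Sum of ventilation, deposition and extra-sink removal, expressed as an
#' air-change-equivalent rate `(Q + lambda * V + sum(sinks)) / V` in 1/h.
#'
#' @param comp A [compartment()].
#' @param sinks A [source_sink_set()] (only its sink flows are used).
#' @return Loss rate, 1/h.
#' @examples
#' total_loss_rate(compartment(20, 10), source_sink_set())
#' @export
total_loss_rate <- function(comp, sinks = source_sink_set()) {
  stopifnot(inherits(comp, "compartment"), inherits(sinks, "source_sink_set"))
  (comp$flow_m3h + comp$deposition_per_h * comp$volume_m3 +
    sum(sinks$sink_flows_m3h)) / comp$volume_m3
}

#' Steady-state concentration of the well-mixed compartment
#'
#' `(G + P * Q * C_out) / (Q + lambda * V + sum(sinks))`. Requires a strictly
#' positive total loss rate: with no removal pathway a constant source
#' accumulates without bound and no steady state exists.
#'
#' @inheritParams total_loss_rate
#' @return Steady-state concentration in the state unit.
#' @examples
#' # two purifiers' worth of source in a 20 m3 room at 0.5 1/h
#' steady_state(compartment(20, 10), source_sink_set(rate = 0.1998))
#' @export
steady_state <- function(comp, sinks = source_sink_set()) {
  k <- total_loss_rate(comp, sinks)
  if (k <= 0) {
    abort(paste0(
      "No steady state: total loss rate is zero ",
      "(no ventilation, deposition or sink removes particles)."
    ))
  }
  (sinks$rate + comp$penetration * comp$flow_m3h * comp$outdoor_conc) /
    (k * comp$volume_m3)
}

#' Solve the compartment concentration profile
#'
#' Closed-form exponential relaxation
#' `C(t) = C_ss + (C0 - C_ss) exp(-k t)` for constant coefficients (the
#' primary path), or adaptive numerical integration (`method = "ode"`,
#' relative tolerance 1e-10) which serves as an independent check and as the
#' route for future time-varying inputs. With zero total loss the profile is
#' the linear accumulation `C0 + (G + P Q C_out) t / V` and the steady state
#' is reported as `NA`.
#'
#' @inheritParams total_loss_rate
#' @param init_conc Initial concentration `C0` (>= 0), state unit.
#' @param times_h Strictly increasing time grid in hours starting at 0.
#' @param method `"analytic"` (default) or `"ode"`.
#' @return A tibble of class `solution_profile` with columns `time_h` and
#'   `conc`, and attributes `steady_state` and `loss_rate_per_h`.
#' @examples
#' comp <- compartment(20, 10)
#' prof <- solve_profile(comp, source_sink_set(rate = 0.1998),
#'   init_conc = 0, times_h = seq(0, 10, by = 0.5)
#' )
#' attr(prof, "steady_state")
#' @export
solve_profile <- function(comp, sinks = source_sink_set(), init_conc = 0,
                          times_h = seq(0, 10, by = 0.1),
                          method = c("analytic", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(comp, "compartment"), inherits(sinks, "source_sink_set"))
  if (init_conc < 0) abort("`init_conc` must be non-negative.")
  if (length(times_h) < 1 || times_h[1] != 0 ||
    (length(times_h) > 1 && any(diff(times_h) <= 0))) {
    abort("`times_h` must be strictly increasing and start at 0.")
  }
  k <- total_loss_rate(comp, sinks)
  influx <- sinks$rate + comp$penetration * comp$flow_m3h * comp$outdoor_conc
  if (k > 0) {
    c_ss <- influx / (k * comp$volume_m3)
    conc <- switch(method,
      analytic = c_ss + (init_conc - c_ss) * exp(-k * times_h),
      ode = .ode_profile(comp, sinks, init_conc, times_h)
    )
  } else {
    c_ss <- NA_real_
    conc <- switch(method,
      analytic = init_conc + influx * times_h / comp$volume_m3,
      ode = .ode_profile(comp, sinks, init_conc, times_h)
    )
  }
  new_solution_profile(
    tibble(time_h = times_h, conc = conc),
    steady_state = c_ss, loss_rate_per_h = k
  )
}

# independent numerical route (adaptive lsoda, rtol 1e-10)
.ode_profile <- function(comp, sinks, init_conc, times_h) {
  rhs <- function(t, y, parms) {
    dC <- (sinks$rate +
      comp$penetration * comp$flow_m3h * comp$outdoor_conc -
      (comp$flow_m3h + comp$deposition_per_h * comp$volume_m3 +
        sum(sinks$sink_flows_m3h)) * y[1]) / comp$volume_m3
    list(dC)
  }
  out <- deSolve::ode(
    y = c(C = init_conc), times = times_h, func = rhs, parms = NULL,
    rtol = 1e-10, atol = 1e-14
  )
  unname(out[, "C"])
}

new_solution_profile <- function(df, steady_state, loss_rate_per_h) {
  structure(
    as_tibble(df),
    steady_state = steady_state,
    loss_rate_per_h = loss_rate_per_h,
    class = c("solution_profile", class(as_tibble(df)))
  )
}

#' Closed-chamber linear accumulation
#'
#' Special case of the mass balance with no ventilation and no deposition:
#' `V dC/dt = G`, so `C(t) = C0 + G t / V`. This is the model under which a
#' chamber emission rate is read off a concentration time derivative.
#'
#' @param volume_m3 Chamber volume, m^3.
#' @param rate_per_s Source rate per second (particles/s for a number state,
#'   ng/s for a mass state).
#' @param init_conc Initial concentration in the state unit.
#' @param times_s Times in seconds.
#' @param metric `"number"` (state 1/cm^3) or `"mass"` (state ng/m^3);
#'   controls the volume unit so that `rate / volume` lands in the state
#'   unit per second.
#' @return Tibble with `time_s` and `conc`.
#' @examples
#' # 220 L chamber emitting 4400 particles/s: slope 0.02 1/(cm3 s)
#' closed_chamber_profile(0.22, 4400, 0, c(0, 60))
#' @export
closed_chamber_profile <- function(volume_m3, rate_per_s, init_conc = 0,
                                   times_s, metric = c("number", "mass")) {
  metric <- match.arg(metric)
  stopifnot(volume_m3 > 0)
  v_state <- state_volume(volume_m3, metric)
  tibble(time_s = times_s, conc = init_conc + rate_per_s * times_s / v_state)
}

#' @export
print.compartment <- function(x, ...) {
  cat(
    "<compartment> V =", x$volume_m3, "m3, Q =", x$flow_m3h,
    "m3/h, P =", x$penetration, ", lambda =", x$deposition_per_h,
    "1/h, C_out =", x$outdoor_conc, "\n"
  )
  invisible(x)
}

#' @rdname solve_profile
#' @param x A `solution_profile`.
#' @param object A `solution_profile`.
#' @param ... Unused.
#' @method autoplot solution_profile
#' @export
autoplot.solution_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time_h, y = .data$conc)) +
    geom_line() +
    labs(x = "time (h)", y = "concentration") +
    theme_minimal()
  c_ss <- attr(object, "steady_state")
  if (is.finite(c_ss)) {
    p <- p + geom_hline(yintercept = c_ss, linetype = "dashed")
  }
  p
}

#' @rdname solve_profile
#' @method glance solution_profile
#' @export
glance.solution_profile <- function(x, ...) {
  tibble(
    steady_state = attr(x, "steady_state"),
    loss_rate_per_h = attr(x, "loss_rate_per_h"),
    final_conc = x$conc[nrow(x)],
    duration_h = x$time_h[nrow(x)]
  )
}
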