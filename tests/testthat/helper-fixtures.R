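# Shared fixtures, all built in code.

# the two LOQ-censored gravimetric campaigns from the reference study
reference_samples <- function() {
  filter_samples(
    label = c("Test 2A", "Test 2B"),
    censored = TRUE, loq_ng = 1,
    volume_m3 = c(303.7, 229.6), duration_h = c(96, 72)
  )
}

# 20 m3 room at 0.5 1/h with two purifiers (three 90 cm2 honeycombs each)
# recirculating 10 m3/h each and emitting at the bounded release factor
reference_scenario <- function(efficiency = 0, release_factor = 0.185) {
  room_scenario(
    room_volume_m3 = 20, ach_per_h = 0.5,
    purifiers = rep(
      list(purifier(
        flow_m3h = 10, surface = surface_spec(3, 0.009),
        release_factor = release_factor,
        filtration_efficiency = efficiency
      )),
      2
    ),
    duration_h = 10
  )
}

# noiseless linearly rising chamber record
linear_series <- function(slope_per_s = 0.02, c0 = 5, n = 400, dt = 10) {
  t <- seq(0, by = dt, length.out = n)
  conc_series(t, c0 + slope_per_s * t)
}

random_compartment_case <- function() {
  list(
    comp = compartment(
      volume_m3 = runif(1, 1, 500),
      flow_m3h = runif(1, 0, 50),
      penetration = runif(1),
      deposition_per_h = runif(1, 0, 2),
      outdoor_conc = runif(1, 0, 20)
    ),
    sinks = source_sink_set(
      rate = runif(1, 0, 100),
      sink_flows_m3h = runif(sample(0:3, 1), 0, 30)
    ),
    c0 = runif(1, 0, 50)
  )
}
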