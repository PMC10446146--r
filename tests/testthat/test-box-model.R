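test_that("total loss rate sums ventilation, deposition and sinks", {
  expect_equal(
    total_loss_rate(compartment(20, 10), source_sink_set()),
    0.5
  )
  # sealed chamber: no ventilation, no deposition
  expect_equal(
    total_loss_rate(compartment(0.22, 0), source_sink_set()),
    0
  )
  # Q = 10, V = 20, lambda = 0.1 1/h, one sink at 50% of 20 m3/h
  expect_equal(
    total_loss_rate(
      compartment(20, 10, deposition_per_h = 0.1),
      source_sink_set(sink_flows_m3h = 10)
    ),
    (10 + 2 + 10) / 20
  )
})

test_that("steady state matches the source/removal balance", {
  comp <- compartment(20, 10)
  expect_equal(steady_state(comp, source_sink_set(rate = 0)), 0)
  # the reference room: 0.1998 ng/h into 10 m3/h of removal
  expect_equal(steady_state(comp, source_sink_set(rate = 0.1998)), 0.01998)
  # doubling ventilation halves the steady state
  expect_equal(
    steady_state(compartment(20, 20), source_sink_set(rate = 1)),
    steady_state(comp, source_sink_set(rate = 1)) / 2
  )
  expect_error(
    steady_state(compartment(0.22, 0), source_sink_set(rate = 1)),
    "No steady state"
  )
})

test_that("closed-form profile relaxes exponentially to steady state", {
  comp <- compartment(20, 10)
  sinks <- source_sink_set(rate = 0.1998)
  c_ss <- steady_state(comp, sinks)

  # starting at the fixed point stays there
  flat <- solve_profile(comp, sinks, init_conc = c_ss, times_h = 0:10)
  expect_equal(flat$conc, rep(c_ss, 11))

  prof <- solve_profile(comp, sinks, init_conc = 0, times_h = c(0, 10))
  expect_equal(prof$conc[2], 0.01998 * (1 - exp(-5)), tolerance = 1e-12)

  # t -> infinity limit: 20 e-foldings from steady state
  k <- attr(prof, "loss_rate_per_h")
  far <- solve_profile(comp, sinks, init_conc = 0, times_h = c(0, 20 / k))
  expect_lt(abs(far$conc[2] - c_ss), 1e-8 * c_ss)

  expect_error(solve_profile(comp, sinks, init_conc = -1), "non-negative")
  expect_error(
    solve_profile(comp, sinks, times_h = c(1, 2)),
    "start at 0"
  )
})

test_that("closed form agrees with the numerical integrator", {
  withr::local_seed(42)
  worst <- 0
  for (i in 1:100) {
    case <- random_compartment_case()
    times <- sort(c(0, runif(8, 0, 24)))
    a <- solve_profile(case$comp, case$sinks, case$c0, times,
      method = "analytic"
    )
    b <- solve_profile(case$comp, case$sinks, case$c0, times,
      method = "ode"
    )
    scale <- pmax(abs(a$conc), 1e-6)
    worst <- max(worst, max(abs(a$conc - b$conc) / scale))
  }
  expect_lt(worst, 1e-9)
})

test_that("steady state is monotone in source and ventilation", {
  g <- seq(0.5, 5, by = 0.5)
  ss_g <- vapply(
    g,
    function(gi) steady_state(compartment(20, 10), source_sink_set(rate = gi)),
    numeric(1)
  )
  expect_true(all(diff(ss_g) > 0))
  q <- seq(1, 30, by = 1)
  ss_q <- vapply(
    q,
    function(qi) steady_state(compartment(20, qi), source_sink_set(rate = 1)),
    numeric(1)
  )
  expect_true(all(diff(ss_q) < 0))
})

test_that("closed chamber accumulates linearly and conserves mass", {
  # zero source: constant concentration
  expect_equal(
    closed_chamber_profile(0.22, 0, init_conc = 7, times_s = 0:10)$conc,
    rep(7, 11)
  )
  # 220 L chamber at 4400 1/s: slope 0.02 1/(cm3 s), 1.2 1/cm3 after 60 s
  prof <- closed_chamber_profile(0.22, 4400, init_conc = 0, times_s = c(0, 60))
  expect_equal(prof$conc[2], 1.2)
  # conservation: V (C - C0) = G t exactly, V in the state volume unit
  t <- seq(0, 3600, by = 60)
  prof <- closed_chamber_profile(0.22, 4400, init_conc = 3, times_s = t)
  expect_equal((prof$conc - 3) * 0.22e6, 4400 * t)
  # mass metric uses the m3 volume directly
  mass <- closed_chamber_profile(20, 0.5, 0, c(0, 3600), metric = "mass")
  expect_equal(mass$conc[2], 0.5 * 3600 / 20)
})

test_that("zero-loss profile grows linearly with steady state undefined", {
  comp <- compartment(0.22, 0)
  prof <- solve_profile(comp, source_sink_set(rate = 10),
    times_h = seq(0, 2, by = 0.5)
  )
  expect_true(is.na(attr(prof, "steady_state")))
  expect_equal(prof$conc, 10 * seq(0, 2, by = 0.5) / 0.22)
})

test_that("profile accessors summarise the solution", {
  prof <- solve_profile(compartment(20, 10), source_sink_set(rate = 0.1998),
    times_h = seq(0, 10, by = 0.1)
  )
  g <- glance(prof)
  expect_equal(g$steady_state, 0.01998)
  expect_equal(g$loss_rate_per_h, 0.5)
  expect_equal(g$duration_h, 10)
  expect_s3_class(ggplot2::autoplot(prof), "ggplot")
})
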