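test_that("chamber simulation is deterministic and carries its truth", {
  cfg <- list(
    true_rate_per_s = 4400, volume_m3 = 0.22, duration_s = 7200,
    dt_s = 10, noise_sd = 0.5, spike_rate_per_h = 3, seed = 11
  )
  a <- do.call(sim_chamber_series, cfg)
  b <- do.call(sim_chamber_series, cfg)
  expect_identical(a$conc, b$conc)
  expect_identical(attr(a, "exclusions"), attr(b, "exclusions"))
  expect_equal(attr(a, "truth")$true_rate_per_s, 4400)

  # a different seed produces a different realisation
  cfg$seed <- 12
  expect_false(identical(do.call(sim_chamber_series, cfg)$conc, a$conc))
})

test_that("noiseless spike-free simulation is an exact line", {
  s <- sim_chamber_series(
    true_rate_per_s = 4400, volume_m3 = 0.22, init_conc = 5,
    duration_s = 3600, dt_s = 10, noise_sd = 0, seed = 1
  )
  expect_equal(s$conc, 5 + 0.02 * s$time_s, tolerance = 1e-12)
  expect_equal(nrow(attr(s, "exclusions")), 0)
})

test_that("infiltration spikes are reported as exclusion ground truth", {
  s <- sim_chamber_series(
    true_rate_per_s = 0, volume_m3 = 0.22, init_conc = 5,
    duration_s = 86400, dt_s = 10, noise_sd = 0,
    spike_rate_per_h = 2, spike_magnitude = 20, spike_decay_per_h = 60,
    seed = 3
  )
  excl <- attr(s, "exclusions")
  expect_gt(nrow(excl), 0)
  # concentration right after a spike arrival clearly exceeds baseline
  first <- excl$start[1]
  after <- s$conc[which(s$time_s >= first)[1]]
  expect_gt(after, 10)
  # masking the truth windows brings the derivative back near zero
  est <- infer_emission(s,
    volume_m3 = 0.22, intervals = excl, window_s = 900
  )
  spiked <- infer_emission(s, volume_m3 = 0.22, window_s = 900)
  expect_lte(est$point, spiked$point)
})

test_that("filter simulation censors below the LOQ and round-trips", {
  # the reference campaign's own bound is unmeasurable at a 1 ng LOQ
  ref <- sim_filter_sample(
    true_rf = 0.185, surface = surface_spec(3, 0.009),
    flow_m3h = 303.7 / 96, duration_h = 96, loq_ng = 1, seed = 5
  )
  expect_true(ref$censored)
  truth <- attr(ref, "truth")
  expect_equal(truth$true_tio2_mass_ng, 0.185 * 0.027 * 303.7)
  expect_lt(truth$true_ti_mass_ng, 1)
  expect_equal(truth$true_ti_mass_ng, tio2_to_ti(truth$true_tio2_mass_ng))

  # zero release is always censored
  z <- sim_filter_sample(0,
    flow_m3h = 3, duration_h = 96, loq_ng = 1, seed = 1
  )
  expect_true(z$censored)

  # a strong emitter is quantifiable and its release factor is recovered
  hot <- sim_filter_sample(
    true_rf = 10, surface = surface_spec(3, 0.009),
    flow_m3h = 303.7 / 96, duration_h = 96, loq_ng = 1, seed = 5
  )
  expect_false(hot$censored)
  rf <- release_factors(hot, surface_spec(3, 0.009))
  expect_equal(rf$rf_tio2, 10, tolerance = 1e-10)
  expect_false(rf$is_upper_bound)
})

test_that("censoring boundary: mass exactly at the LOQ is quantifiable", {
  # power-of-two geometry keeps the arithmetic exact in floating point,
  # so the Ti mass lands exactly on the 1 ng LOQ
  surface <- surface_spec(1, 0.25)
  flow <- 4
  duration <- 16
  rf_at_loq <- ti_to_tio2(1) / (surface$total_area_m2 * flow * duration)
  s <- sim_filter_sample(rf_at_loq,
    surface = surface,
    flow_m3h = flow, duration_h = duration, loq_ng = 1, seed = 1
  )
  expect_false(s$censored)
  expect_identical(s$ti_mass_ng, 1)
  # one representable notch below the LOQ is censored
  s2 <- sim_filter_sample(rf_at_loq * (1 - 1e-9),
    surface = surface,
    flow_m3h = flow, duration_h = duration, loq_ng = 1, seed = 1
  )
  expect_true(s2$censored)
})

test_that("noisy filter measurements recover the release factor in median", {
  surface <- surface_spec(3, 0.009)
  rfs <- vapply(1:40, function(i) {
    s <- sim_filter_sample(
      true_rf = 10, surface = surface, flow_m3h = 3, duration_h = 96,
      loq_ng = 1, noise_sdlog = 0.1, seed = i
    )
    release_factors(s, surface)$rf_tio2
  }, numeric(1))
  expect_equal(median(rfs), 10, tolerance = 0.05)
})

test_that("recovery experiment has zero bias without noise", {
  out <- recovery_experiment(
    n_reps = 10,
    config = list(
      true_rate_per_s = 4400, volume_m3 = 0.22,
      duration_s = 36000, dt_s = 10, noise_sd = 0
    ),
    seed = 1
  )
  expect_equal(out$summary$median_rel_bias, 0, tolerance = 1e-10)
  expect_equal(out$summary$coverage, 1)
  expect_equal(nrow(out$results), 10)
})

test_that("generators leave the caller's RNG stream untouched", {
  withr::local_seed(99)
  before <- rnorm(1)
  withr::local_seed(99)
  invisible(sim_chamber_series(
    true_rate_per_s = 1, volume_m3 = 1, duration_s = 100, dt_s = 1,
    noise_sd = 1, seed = 7
  ))
  after <- rnorm(1)
  expect_identical(before, after)
})
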