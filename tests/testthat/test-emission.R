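test_that("masking removes samples and records the gap", {
  s <- conc_series(0:99, rep(5, 100))
  expect_identical(
    mask_series(s, exclusion_intervals()),
    s
  )
  masked <- mask_series(s, exclusion_intervals(39.5, 60.5))
  expect_equal(nrow(masked), 79)
  expect_equal(length(unique(masked$block)), 2)
  expect_false(any(masked$time_s >= 39.5 & masked$time_s <= 60.5))
  expect_error(
    mask_series(s, exclusion_intervals(-1, 1000)),
    "every sample"
  )
})

test_that("overlapping exclusion intervals are merged", {
  iv <- exclusion_intervals(c(10, 15, 40), c(20, 30, 50))
  expect_equal(iv$start, c(10, 40))
  expect_equal(iv$end, c(30, 50))
  expect_error(exclusion_intervals(5, 5), "start < end")
})

test_that("block averaging preserves constants and linear ramps", {
  const <- conc_series(seq(0, 3599), rep(3.5, 3600))
  avg <- block_average(const, 900)
  expect_equal(nrow(avg), 4)
  expect_equal(avg$conc, rep(3.5, 4))

  # on a linear ramp the window means lie exactly on the ramp at centres
  # (samples are left-aligned in each window, so the sample mean sits half
  # a step before the window centre)
  ramp <- conc_series(seq(0, 3599), 2 + 0.01 * seq(0, 3599))
  avg <- block_average(ramp, 900)
  sample_centres <- tapply(ramp$time_s, floor(ramp$time_s / 900), mean)
  expect_equal(avg$conc, as.numeric(2 + 0.01 * sample_centres))

  expect_error(block_average(conc_series(0:9, 0:9), 1), "twice the median")
})

test_that("windows spanning a masked gap are dropped", {
  s <- conc_series(seq(0, 3599), rep(1, 3600))
  masked <- mask_series(s, exclusion_intervals(1000, 1100))
  avg <- block_average(masked, 900)
  # the window holding the gap (1000-1100 s lies in window 900-1800) is gone
  expect_equal(nrow(avg), 3)
  expect_false(any(avg$time_s > 900 & avg$time_s < 1800))
})

test_that("derivative of a noiseless line recovers the slope exactly", {
  s <- linear_series(slope_per_s = 0.02)
  st <- derivative_stats(s)
  expect_equal(st$mean, 0.02, tolerance = 1e-10)
  expect_equal(st$sd, 0, tolerance = 1e-10)

  avg <- block_average(linear_series(0.02, n = 3600, dt = 1), 60)
  st2 <- derivative_stats(avg)
  expect_equal(st2$mean, 0.02, tolerance = 1e-10)

  const <- derivative_stats(conc_series(0:9, rep(4, 10)))
  expect_equal(const$mean, 0)
  expect_equal(const$sd, 0)

  expect_error(derivative_stats(conc_series(0:1, c(1, 2))), "at least 3")
})

test_that("derivatives never straddle a masked gap", {
  # big jump hidden inside the masked window must not leak into the stats
  t <- seq(0, 1999)
  conc <- c(rep(1, 1000), rep(100, 1000))
  s <- mask_series(
    conc_series(t, conc),
    exclusion_intervals(995.5, 1004.5)
  )
  st <- derivative_stats(s)
  expect_equal(st$mean, 0)
  expect_equal(st$sd, 0)
})

test_that("emission bound scales the derivative by the chamber volume", {
  # reported chamber statistics: mean 1e-4, sd 0.02 1/(cm3 s), V = 220 L
  b <- emission_bound(derivative_record(1e-4, 0.02), volume_m3 = 0.22)
  expect_equal(round_sig(b$upper, 2), 4400)
  expect_equal(b$point, 1e-4 * 0.22e6)

  # zero spread: upper equals the point estimate
  b0 <- emission_bound(derivative_record(2e-4, 0), volume_m3 = 0.22)
  expect_equal(b0$upper, b0$point)

  # net decay floors at zero
  bneg <- emission_bound(derivative_record(-0.01, 0.005), volume_m3 = 1)
  expect_equal(bneg$point, 0)
  expect_equal(bneg$upper, 0)

  # k_sigma widens the range
  b2 <- emission_bound(derivative_record(1e-4, 0.02),
    volume_m3 = 0.22, k_sigma = 2
  )
  expect_equal(b2$upper, (1e-4 + 2 * 0.02) * 0.22e6)
})

test_that("masking before or after averaging gives the same estimate", {
  withr::local_seed(7)
  t <- seq(0, 7199)
  s <- conc_series(t, 5 + 0.001 * t + abs(rnorm(length(t), 0, 0.2)))
  iv <- exclusion_intervals(c(1000, 4000), c(1200, 4300))
  a <- derivative_stats(block_average(mask_series(s, iv), 900))
  # dropping the affected windows by hand gives the same usable diffs
  avg_all <- block_average(s, 900)
  bad <- unique(floor(c(1000, 1200, 4000, 4300) / 900))
  keep <- !(floor(avg_all$time_s / 900) %in% bad)
  manual <- avg_all[keep, ]
  d <- diff(manual$conc) / diff(manual$time_s)
  d <- d[diff(manual$window) == 1]
  expect_equal(a$mean, mean(d), tolerance = 1e-6)
})

test_that("full inference pipeline recovers a noiseless source exactly", {
  # 4400 1/s in a 220 L chamber: slope 0.02 1/(cm3 s)
  s <- linear_series(slope_per_s = 0.02, n = 8640, dt = 10)
  est <- infer_emission(s, volume_m3 = 0.22)
  expect_equal(est$point, 4400, tolerance = 1e-10)
  expect_equal(est$upper, 4400, tolerance = 1e-10)
})
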