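# Synthetic data with known ground truth. The chamber generator emulates a
# sealed-chamber number-concentration record: a slow linear rise from a
# constant source, additive instrument noise, and intermittent
# infiltration spikes (brief external sampling draws replacement lab air
# into the chamber, producing sharp transients that decay away). The
# filter generator emulates a gravimetric sampling campaign with a known
# true release factor and an assay LOQ. Everything is driven by one
# integer seed and returns the truth alongside the data.

#' Simulate a chamber concentration time series
#'
#' Signal `C0 + G t / V` plus independent Gaussian noise (truncated at
#' zero) plus Poisson-arriving, exponentially decaying spikes. The spike
#' windows are returned as exclusion-interval ground truth so masking can
#' be tested against them.
#'
#' @param true_rate_per_s True source rate, particles/s.
#' @param volume_m3 Chamber volume, m^3.
#' @param init_conc Initial concentration, 1/cm^3.
#' @param duration_s Record length, s (>= 10 sampling intervals).
#' @param dt_s Sampling interval, s.
#' @param noise_sd Additive Gaussian noise sd, 1/cm^3.
#' @param spike_rate_per_h Poisson arrival rate of infiltration spikes,
#'   1/h (0 disables spikes).
#' @param spike_magnitude Initial spike amplitude, 1/cm^3.
#' @param spike_decay_per_h Spike decay rate, 1/h.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A [conc_series()] with attributes `truth` (the generating
#'   parameters) and `exclusions` (spike windows, from arrival until decay
#'   below 1% of the spike magnitude).
#' @examples
#' s <- sim_chamber_series(
#'   true_rate_per_s = 4400, volume_m3 = 0.22,
#'   duration_s = 3600, dt_s = 10, noise_sd = 0, seed = 1
#' )
#' attr(s, "truth")$true_rate_per_s
#' @export
sim_chamber_series <- function(true_rate_per_s, volume_m3 = 0.22,
                               init_conc = 5, duration_s = 259200,
                               dt_s = 10, noise_sd = 0,
                               spike_rate_per_h = 0, spike_magnitude = 10,
                               spike_decay_per_h = 30, seed = 1) {
  stopifnot(
    true_rate_per_s >= 0, volume_m3 > 0, dt_s > 0,
    duration_s >= 10 * dt_s, noise_sd >= 0, spike_rate_per_h >= 0,
    spike_magnitude >= 0, spike_decay_per_h > 0
  )
  rng <- local_rng(seed, "chamber")
  time_s <- seq(0, duration_s, by = dt_s)
  v_cm3 <- state_volume(volume_m3, "number")
  signal <- init_conc + true_rate_per_s * time_s / v_cm3
  if (noise_sd > 0) {
    signal <- signal + rnorm(length(time_s), 0, noise_sd)
  }
  excl <- tibble(start = numeric(0), end = numeric(0))
  if (spike_rate_per_h > 0 && spike_magnitude > 0) {
    n_spikes <- rpois(1, spike_rate_per_h * duration_s / 3600)
    if (n_spikes > 0) {
      arrivals <- sort(runif(n_spikes, 0, duration_s))
      decay_per_s <- spike_decay_per_h / 3600
      for (a in arrivals) {
        after <- time_s >= a
        signal[after] <- signal[after] +
          spike_magnitude * exp(-decay_per_s * (time_s[after] - a))
      }
      # window until the spike has decayed below 1% of its magnitude
      excl <- exclusion_intervals(
        start = arrivals,
        end = arrivals + log(100) / decay_per_s
      )
    }
  }
  out <- conc_series(time_s, pmax(signal, 0),
    metric = "number",
    instrument = "synthetic"
  )
  structure(
    out,
    truth = list(
      true_rate_per_s = true_rate_per_s, volume_m3 = volume_m3,
      init_conc = init_conc, duration_s = duration_s, dt_s = dt_s,
      noise_sd = noise_sd, spike_rate_per_h = spike_rate_per_h,
      spike_magnitude = spike_magnitude,
      spike_decay_per_h = spike_decay_per_h, seed = seed
    ),
    exclusions = excl,
    metric = "number", instrument = "synthetic",
    class = class(out)
  )
}

#' Simulate a gravimetric filter sample
#'
#' The collected TiO2 mass is `true_rf * total_area * flow * duration`;
#' the Ti mass on the filter is its molar-mass back-conversion, optionally
#' perturbed by multiplicative lognormal measurement noise
#' (median-preserving, `meanlog = 0`). The sample is censored when the Ti
#' mass falls strictly below the LOQ (mass exactly at the LOQ is
#' quantifiable, hence uncensored).
#'
#' @param true_rf True TiO2 release factor, ng/(m^2 m^3).
#' @param surface A [surface_spec()].
#' @param flow_m3h Sampling flow, m^3/h.
#' @param duration_h Sampling duration, h.
#' @param loq_ng Assay limit of quantification, ng.
#' @param noise_sdlog Lognormal sdlog of the measurement noise (0 = exact).
#' @param seed Integer seed.
#' @param label Sample label.
#' @return A [filter_samples()] row with attribute `truth` (including the
#'   noiseless `true_ti_mass_ng`).
#' @examples
#' # the reported release bound is itself unmeasurable at a 1 ng LOQ
#' s <- sim_filter_sample(0.185, flow_m3h = 303.7 / 96, duration_h = 96)
#' s$censored
#' @export
sim_filter_sample <- function(true_rf, surface = surface_spec(),
                              flow_m3h, duration_h, loq_ng = 1,
                              noise_sdlog = 0, seed = 1,
                              label = "synthetic") {
  stopifnot(
    true_rf >= 0, inherits(surface, "surface_spec"),
    flow_m3h > 0, duration_h > 0, loq_ng > 0, noise_sdlog >= 0
  )
  rng <- local_rng(seed, "filter")
  volume_m3 <- flow_m3h * duration_h
  tio2_ng <- true_rf * surface$total_area_m2 * volume_m3
  ti_ng <- tio2_to_ti(tio2_ng)
  observed <- if (noise_sdlog > 0) {
    ti_ng * rlnorm(1, meanlog = 0, sdlog = noise_sdlog)
  } else {
    ti_ng
  }
  censored <- observed < loq_ng
  out <- filter_samples(
    label = label,
    ti_mass_ng = if (censored) NA_real_ else observed,
    censored = censored, loq_ng = loq_ng,
    volume_m3 = volume_m3, duration_h = duration_h
  )
  structure(
    out,
    truth = list(
      true_rf = true_rf, true_ti_mass_ng = ti_ng,
      true_tio2_mass_ng = tio2_ng, surface = surface,
      flow_m3h = flow_m3h, duration_h = duration_h,
      loq_ng = loq_ng, noise_sdlog = noise_sdlog, seed = seed
    ),
    class = class(out)
  )
}

#' Parameter-recovery experiment for the emission estimator
#'
#' Repeatedly simulates a chamber record with a known source rate, runs the
#' full inference pipeline (block averaging, windowed derivative, volume
#' scaling), and summarises the point estimate's relative bias and how
#' often the k-sigma upper range covers the truth.
#'
#' @param n_reps Number of replicates (>= 10).
#' @param config Named list of [sim_chamber_series()] arguments (the
#'   template; `seed` is supplied per replicate).
#' @param window_s Averaging window for the estimator, s.
#' @param k_sigma Upper-range multiplier.
#' @param seed Integer master seed; replicate seeds derive from it.
#' @return List with `results` (per-replicate tibble: `rep`, `point`,
#'   `upper`, `rel_bias`, `covered`) and `summary` (one-row tibble:
#'   `median_rel_bias`, `median_abs_rel_bias`, `coverage`).
#' @examples
#' recovery_experiment(
#'   n_reps = 10,
#'   config = list(
#'     true_rate_per_s = 4400, volume_m3 = 0.22,
#'     duration_s = 36000, dt_s = 10, noise_sd = 0
#'   ),
#'   seed = 1
#' )$summary
#' @export
recovery_experiment <- function(n_reps, config, window_s = 900,
                                k_sigma = 1, seed = 1) {
  stopifnot(n_reps >= 10, is.list(config))
  true_g <- config$true_rate_per_s
  volume_m3 <- config$volume_m3 %||% 0.22
  rng <- local_rng(seed, "recovery")
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  results <- purrr::map_dfr(seq_len(n_reps), function(i) {
    args <- config
    args$seed <- rep_seeds[i]
    series <- do.call(sim_chamber_series, args)
    est <- series |>
      mask_series(attr(series, "exclusions")) |>
      block_average(window_s) |>
      derivative_stats() |>
      emission_bound(volume_m3 = volume_m3, k_sigma = k_sigma)
    tibble(
      rep = i, point = est$point, upper = est$upper,
      rel_bias = if (true_g > 0) (est$point - true_g) / true_g else NA_real_,
      # 1e-9 relative slack so exact noiseless recovery counts as covered
      covered = est$upper >= true_g * (1 - 1e-9)
    )
  })
  list(
    results = results,
    summary = tibble(
      n_reps = n_reps,
      median_rel_bias = median(results$rel_bias),
      median_abs_rel_bias = median(abs(results$rel_bias)),
      coverage = mean(results$covered)
    )
  )
}

# One named random stream per generator from a single integer seed; the
# caller's RNG state is restored on exit. Stream offsets keep generators
# independent even when handed the same seed.
local_rng <- function(seed, stream = c("chamber", "filter", "recovery")) {
  stream <- match.arg(stream)
  offset <- c(chamber = 0L, filter = 11L, recovery = 29L)[[stream]]
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
  withr::defer(restore(), envir = parent.frame())
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  invisible(seed)
}
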