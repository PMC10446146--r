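# Chamber emission-rate inference from a concentration time series.
# The closed-chamber balance V dC/dt = G means the source rate is the mean
# time derivative of the (block-averaged) concentration, scaled by chamber
# volume; the spread of the window-to-window derivatives gives an upper
# range. Samples taken while an external instrument perturbed the chamber
# are masked first, and no derivative ever spans a masked gap.

#' Build a concentration time series
#'
#' The common container for instrument time series: one instrument, one
#' metric, strictly increasing timestamps in seconds. A `block` column
#' tracks contiguous runs of samples; masking splits blocks so downstream
#' averaging and differencing never bridge a gap.
#'
#' @param time_s Timestamps in elapsed seconds, strictly increasing.
#' @param conc Concentrations (>= 0), in 1/cm^3 for `metric = "number"` or
#'   ng/m^3 for `metric = "mass"`.
#' @param metric `"number"` or `"mass"`.
#' @param instrument Optional instrument label.
#' @return A tibble of class `conc_series` with columns `time_s`, `conc`,
#'   `block`.
#' @examples
#' conc_series(0:9, rep(5, 10))
#' @export
conc_series <- function(time_s, conc, metric = c("number", "mass"),
                        instrument = NA_character_) {
  metric <- match.arg(metric)
  time_s <- as.numeric(time_s)
  conc <- as.numeric(conc)
  if (length(time_s) != length(conc)) {
    abort("`time_s` and `conc` must have the same length.")
  }
  if (length(time_s) < 1) abort("series must contain at least one sample.")
  if (any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing.")
  }
  bad <- which(conc < 0 | is.na(conc))
  if (length(bad)) {
    abort(paste0(
      "negative or missing concentration at row(s) ",
      paste(head(bad, 5), collapse = ", "), "."
    ))
  }
  new_conc_series(
    tibble(time_s = time_s, conc = conc, block = 1L),
    metric = metric, instrument = instrument
  )
}

new_conc_series <- function(df, metric, instrument = NA_character_) {
  structure(
    as_tibble(df),
    metric = metric, instrument = instrument,
    class = c("conc_series", class(as_tibble(df)))
  )
}

series_metric <- function(series) attr(series, "metric") %||% "number"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exclusion intervals for masking a series
#'
#' Normalises a set of `[start, end]` second windows: merges overlaps and
#' orders them. Used to remove samples perturbed by, e.g., brief external
#' counter sampling that draws replacement air into the chamber.
#'
#' @param start,end Interval bounds in seconds (`start < end`, pairwise).
#' @return Tibble with columns `start`, `end`, non-overlapping and sorted.
#' @export
exclusion_intervals <- function(start = numeric(0), end = numeric(0)) {
  if (length(start) != length(end)) {
    abort("`start` and `end` must have the same length.")
  }
  if (any(start >= end)) abort("each interval needs `start < end`.")
  iv <- tibble(start = as.numeric(start), end = as.numeric(end)) |>
    arrange(.data$start)
  if (nrow(iv) > 1) {
    merged <- list(c(iv$start[1], iv$end[1]))
    for (i in seq(2, nrow(iv))) {
      last <- merged[[length(merged)]]
      if (iv$start[i] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], iv$end[i]))
      } else {
        merged[[length(merged) + 1]] <- c(iv$start[i], iv$end[i])
      }
    }
    iv <- tibble(
      start = vapply(merged, `[`, numeric(1), 1),
      end = vapply(merged, `[`, numeric(1), 2)
    )
  }
  iv
}

#' Mask samples inside exclusion intervals
#'
#' Removes every sample whose timestamp falls inside any interval
#' (inclusive bounds) and splits the series into blocks at each gap, so
#' later derivatives cannot straddle the removed stretch.
#'
#' @param series A [conc_series()].
#' @param intervals Output of [exclusion_intervals()] (or a data frame with
#'   `start`/`end` columns in seconds).
#' @return The masked `conc_series`.
#' @export
mask_series <- function(series, intervals) {
  stopifnot(inherits(series, "conc_series"))
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(series)
  }
  intervals <- exclusion_intervals(intervals$start, intervals$end)
  keep <- rep(TRUE, nrow(series))
  for (i in seq_len(nrow(intervals))) {
    keep <- keep &
      !(series$time_s >= intervals$start[i] &
        series$time_s <= intervals$end[i])
  }
  if (!any(keep)) abort("masking removed every sample in the series.")
  out <- series[keep, ]
  # new block after every run of dropped samples
  dropped_before <- cumsum(!keep)[keep]
  out$block <- series$block[keep] * 0L + 1L +
    cumsum(c(0L, diff(dropped_before) > 0 | diff(series$block[keep]) > 0))
  new_conc_series(out,
    metric = series_metric(series),
    instrument = attr(series, "instrument")
  )
}

#' Block-average a series into fixed windows
#'
#' Non-overlapping windows of `window_s` seconds anchored at the first
#' timestamp; each output point is the mean of the samples in its window,
#' timestamped at the window centre. Windows that span a masked gap and
#' windows only partially covered by samples (such as a truncated trailing
#' window) are dropped, and window adjacency is retained so derivatives
#' are only taken between consecutive windows of the same block.
#'
#' @param series A [conc_series()].
#' @param window_s Window length in seconds (>= 2x the median sampling
#'   interval). Default 900 s (15 min).
#' @return A `conc_series` of window means (with a `window` column).
#' @export
block_average <- function(series, window_s = 900) {
  stopifnot(inherits(series, "conc_series"))
  if (nrow(series) > 1) {
    med_dt <- median(diff(series$time_s))
    if (window_s < 2 * med_dt) {
      abort(paste0(
        "`window_s` (", window_s, " s) must be at least twice the median ",
        "sampling interval (", med_dt, " s)."
      ))
    }
  }
  t0 <- series$time_s[1]
  med_dt <- if (nrow(series) > 1) median(diff(series$time_s)) else window_s
  out <- series |>
    mutate(window = floor((.data$time_s - t0) / window_s)) |>
    group_by(.data$window) |>
    summarise(
      span = max(.data$time_s) - min(.data$time_s),
      conc = mean(.data$conc),
      n_blocks = length(unique(.data$block)),
      block = .data$block[1],
      time_s = t0 + (.data$window[1] + 0.5) * window_s,
      .groups = "drop"
    ) |>
    # windows spanning a masked gap, or only partially covered (e.g. a
    # truncated trailing window), are dropped rather than averaged
    filter(.data$n_blocks == 1, .data$span >= window_s - 1.5 * med_dt) |>
    arrange(.data$window)
  if (nrow(out) == 0) abort("no complete windows remain after averaging.")
  new_conc_series(
    out[, c("time_s", "conc", "block", "window")],
    metric = series_metric(series),
    instrument = attr(series, "instrument")
  )
}

#' Summarise the time derivative of a series
#'
#' Finite differences `(C[i+1] - C[i]) / (t[i+1] - t[i])` over consecutive
#' points of the same block (and, for block-averaged input, consecutive
#' windows only), summarised as their mean, sample (n-1) standard deviation
#' and count.
#'
#' @param series A [conc_series()], typically block-averaged.
#' @return One-row tibble of class `derivative_stats`: `mean`, `sd`
#'   (state-unit per second), `n_windows`, `window_s`.
#' @export
derivative_stats <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  if (nrow(series) < 3) {
    abort("need at least 3 points to summarise a derivative.")
  }
  same_block <- diff(series$block) == 0
  if ("window" %in% names(series)) {
    same_block <- same_block & diff(series$window) == 1
  }
  d <- diff(series$conc) / diff(series$time_s)
  d <- d[same_block]
  if (length(d) < 2) {
    abort("fewer than 2 usable consecutive differences.")
  }
  window_s <- if ("window" %in% names(series)) {
    median(diff(series$time_s))
  } else {
    NA_real_
  }
  derivative_record(
    mean = mean(d), sd = sd(d), n_windows = length(d) + 1L,
    window_s = window_s, metric = series_metric(series)
  )
}

#' @rdname derivative_stats
#' @param mean,sd Mean and standard deviation of the windowed derivative,
#'   state-unit per second (e.g. 1/(cm^3 s)). Used to build the record
#'   directly from reported statistics.
#' @param n_windows Number of averaged points behind the statistics.
#' @param window_s Averaging window, seconds.
#' @param metric `"number"` or `"mass"`.
#' @export
derivative_record <- function(mean, sd, n_windows = NA_integer_,
                              window_s = NA_real_,
                              metric = c("number", "mass")) {
  metric <- match.arg(metric)
  if (!is.na(sd) && sd < 0) abort("`sd` must be non-negative.")
  structure(
    tibble(
      mean = mean, sd = sd, n_windows = n_windows, window_s = window_s
    ),
    metric = metric,
    class = c("derivative_stats", class(tibble()))
  )
}

#' Emission rate and its k-sigma upper range from derivative statistics
#'
#' Under the closed-chamber balance the source rate is `mean * V` and its
#' upper range `(mean + k_sigma * sd) * V`, with the volume expressed in the
#' unit matching the state (cm^3 for number concentrations, m^3 for mass).
#' Both are floored at zero: a net concentration decay implies losses, not a
#' negative emission.
#'
#' @param stats A [derivative_stats()] / [derivative_record()] row.
#' @param volume_m3 Chamber volume in m^3.
#' @param k_sigma Multiplier on the standard deviation for the upper range
#'   (default 1, i.e. a one-standard-deviation upper range).
#' @return One-row tibble: `point`, `upper` (state quantity per second),
#'   `k_sigma`, `volume_m3`.
#' @examples
#' # reported chamber statistics: mean 1e-4, sd 0.02 1/(cm3 s), 220 L
#' emission_bound(derivative_record(1e-4, 0.02), volume_m3 = 0.22)
#' @export
emission_bound <- function(stats, volume_m3, k_sigma = 1) {
  stopifnot(inherits(stats, "derivative_stats"), volume_m3 > 0, k_sigma >= 0)
  v_state <- state_volume(volume_m3, attr(stats, "metric") %||% "number")
  point <- max(0, stats$mean * v_state)
  upper <- max(0, (stats$mean + k_sigma * stats$sd) * v_state)
  tibble(
    point = point, upper = upper, k_sigma = k_sigma, volume_m3 = volume_m3
  )
}

#' Estimate a chamber emission rate from a raw series in one call
#'
#' Convenience pipeline: mask, block-average, differentiate, scale by
#' chamber volume.
#'
#' @inheritParams mask_series
#' @inheritParams emission_bound
#' @param window_s Averaging window in seconds (default 900).
#' @return As [emission_bound()].
#' @export
infer_emission <- function(series, volume_m3, intervals = NULL,
                           window_s = 900, k_sigma = 1) {
  series |>
    mask_series(intervals) |>
    block_average(window_s) |>
    derivative_stats() |>
    emission_bound(volume_m3 = volume_m3, k_sigma = k_sigma)
}

#' @rdname conc_series
#' @param object A `conc_series`.
#' @param ... Unused.
#' @method autoplot conc_series
#' @export
autoplot.conc_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s / 3600, y = .data$conc)) +
    geom_line(aes(group = .data$block)) +
    labs(
      x = "time (h)",
      y = if (series_metric(object) == "number") {
        "number concentration (1/cm³)"
      } else {
        "mass concentration (ng/m³)"
      }
    ) +
    theme_minimal()
}
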