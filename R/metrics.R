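#' Resample an IBI series onto a regular grid
#'
#' Interval values are positioned at the time of their second beat and
#' linearly interpolated onto a uniform grid spanning the first to the last
#' beat (the opening sub-interval is extended with the first interval value).
#'
#' @param series An IBI tibble with at least 3 beats.
#' @param sample_rate Grid rate, Hz.
#' @return A tibble with columns `time_s`, `ibi_ms`, and attribute
#'   `sample_rate`.
#' @export
interpolate_ibi <- function(series, sample_rate = 10) {
  validate_ibi(series)
  if (nrow(series) < 2L) {
    abort_insufficient("interpolation needs at least 2 intervals (3 beats).")
  }
  beats <- ibi_beat_times(series)
  grid <- seq(beats[1], beats[length(beats)], by = 1 / sample_rate)
  vals <- approx(series$time_s, series$ibi_ms, xout = grid, rule = 2)$y
  out <- tibble(time_s = grid, ibi_ms = vals)
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Moving-window grid over a recording or segment
#'
#' Windows start at the origin and advance by `step`; a trailing partial
#' window is dropped.
#'
#' @param x Either an IBI tibble (the window grid spans its beats) or a single
#'   number giving a segment duration in seconds.
#' @param length,step Window length and hop, s.
#' @param origin Start time of the first window; defaults to the first beat
#'   (or 0 when `x` is a duration).
#' @return A tibble with columns `window`, `start`, `end`.
#' @export
moving_windows <- function(x, length = 30, step = 3, origin = NULL) {
  check_number(length, "length", min = 0, strict_min = TRUE)
  check_number(step, "step", min = 0, max = length, strict_min = TRUE)
  if (is.data.frame(x)) {
    beats <- ibi_beat_times(x)
    origin <- origin %||% beats[1]
    span_end <- beats[base::length(beats)]
  } else {
    check_number(x, "duration", min = 0, strict_min = TRUE)
    origin <- origin %||% 0
    span_end <- origin + x
  }
  if (span_end - origin < length) {
    abort_insufficient(sprintf(
      "segment of %.1f s is shorter than the %.0f-s window.",
      span_end - origin, length))
  }
  starts <- seq(origin, span_end - length, by = step)
  tibble(window = seq_along(starts), start = starts, end = starts + length)
}

#' Time-domain cardiac metrics
#'
#' `rmssd()` is the root mean square of successive differences of the
#' intervals; `mean_hr()` is 60000 divided by the mean interval; and
#' `ln_variance()` is the natural log of the population (N-denominator)
#' variance, the definition used for both the broadband HRV metric and the
#' band-limited RSA metric. `ln_variance()` returns `NA` for degenerate
#' (constant) input rather than `-Inf`.
#'
#' @param x Numeric vector: intervals in ms for `rmssd()` and `mean_hr()`,
#'   regularly sampled values for `ln_variance()`.
#' @return A single number.
#' @examples
#' rmssd(c(800, 810, 790, 830))  # sqrt(700)
#' mean_hr(c(800, 1200))         # 60 bpm
#' @export
rmssd <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  sqrt(mean(diff(x)^2))
}

#' @rdname rmssd
#' @export
mean_hr <- function(x) {
  if (length(x) < 1L) return(NA_real_)
  60000 / mean(x)
}

#' @rdname rmssd
#' @export
ln_variance <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  v <- mean((x - mean(x))^2)
  if (v <= 1e-12) return(NA_real_)
  log(v)
}

#' Dominant respiration frequency from the IBI spectrum
#'
#' The interpolated IBI series is linearly detrended, Hann-windowed,
#' zero-padded, and Fourier transformed; the dominant frequency is the maximum
#' of the power spectrum within `[fmin, fmax]`. RSA is considered valid only
#' when the peak sits at or above 0.12 Hz, the lower edge of the respiratory
#' band.
#'
#' @param reg A regularly sampled series from [interpolate_ibi()].
#' @param fmin,fmax Search band, Hz.
#' @return A list with `freq` (Hz) and `valid` (`freq >= 0.12`).
#' @export
respiration_peak <- function(reg, fmin = 0.05, fmax = 0.5) {
  fs <- attr(reg, "sample_rate") %||% 10
  x <- reg$ibi_ms
  n <- length(x)
  if (n / fs < 60) {
    abort_insufficient("respiration check needs at least 60 s of data.")
  }
  t <- seq_len(n)
  x <- resid(stats::lm.fit(cbind(1, t), x))
  x <- x * e1071::hanning.window(n)
  nfft <- 2^ceiling(log2(4 * n))
  p <- Mod(fft(c(x, rep(0, nfft - n))))^2
  # average over ~4 resolution bins (17 zero-padded bins) so that noise cross
  # terms cannot flip the ordering of nearby spectral peaks
  p <- as.numeric(stats::filter(p, rep(1 / 17, 17), sides = 2, circular = TRUE))
  f <- (seq_len(nfft) - 1) * fs / nfft
  band <- which(f >= fmin & f <= fmax)
  peak <- band[which.max(p[band])]
  freq <- f[peak]
  list(freq = freq, valid = freq >= 0.12)
}

# Per-window metrics for one condition segment. Returns a tibble with one row
# per window; rmssd/hr computed from raw intervals, hrv/rsa from the 10-Hz
# interpolated (and band-pass filtered) series. Filtering is done once per
# segment with reflection padding, so no window is lost to warm-up.
segment_window_metrics <- function(sub, seg_start, seg_end, window_length,
                                   window_step, h, sample_rate,
                                   rmssd_source = c("intervals", "interpolated")) {
  rmssd_source <- match.arg(rmssd_source)
  win <- moving_windows(seg_end - seg_start, length = window_length,
                        step = window_step, origin = seg_start)
  reg <- interpolate_ibi(sub, sample_rate)
  filt <- apply_band_filter(reg$ibi_ms, h)

  # raw-interval windows: both defining beats inside [start, end)
  t2 <- sub$time_s
  t1 <- t2 - sub$ibi_ms / 1000
  v <- sub$ibi_ms
  d2 <- diff(v)^2
  csq <- c(0, cumsum(d2))
  cs <- c(0, cumsum(v))

  grid0 <- reg$time_s[1]
  g <- function(x) cumsum(c(0, x))
  cf1 <- g(filt); cf2 <- g(filt^2)
  cu1 <- g(reg$ibi_ms); cu2 <- g(reg$ibi_ms^2)
  ng <- nrow(reg)

  one_window <- function(ws, we) {
    lo <- findInterval(ws, t1 + 1e-12) + 1L   # first interval with t1 >= ws
    lo <- if (lo > 1L && t1[lo - 1L] >= ws - 1e-12) lo - 1L else lo
    hi <- findInterval(we - 1e-12, t2)        # last interval with t2 < we
    rm_val <- NA_real_; hr_val <- NA_real_; n_i <- 0L
    if (hi >= lo) {
      n_i <- hi - lo + 1L
      hr_val <- 60000 / ((cs[hi + 1L] - cs[lo]) / n_i)
      if (n_i >= 3L) {
        rm_val <- sqrt((csq[hi] - csq[lo]) / (n_i - 1L))
      }
    }
    glo <- max(1L, ceiling((ws - grid0) * sample_rate - 1e-9) + 1L)
    ghi <- min(ng, floor((we - grid0) * sample_rate - 1e-9) + 1L)
    hrv_val <- NA_real_; rsa_val <- NA_real_
    if (ghi - glo + 1L >= 2L) {
      m <- ghi - glo + 1L
      mu <- (cu1[ghi + 1L] - cu1[glo]) / m
      vv <- (cu2[ghi + 1L] - cu2[glo]) / m - mu^2
      hrv_val <- if (vv > 1e-12) log(vv) else NA_real_
      muf <- (cf1[ghi + 1L] - cf1[glo]) / m
      vf <- (cf2[ghi + 1L] - cf2[glo]) / m - muf^2
      rsa_val <- if (vf > 1e-12) log(vf) else NA_real_
      if (rmssd_source == "interpolated" && m >= 3L) {
        seg_vals <- reg$ibi_ms[glo:ghi]
        rm_val <- rmssd(seg_vals[seq(1, m, by = max(1, round(sample_rate *
          mean(v) / 1000)))])
      }
    }
    c(rm_val, hrv_val, rsa_val, hr_val, n_i)
  }
  res <- vapply(seq_len(nrow(win)),
                function(i) one_window(win$start[i], win$end[i]), numeric(5))
  tibble(window = win$window, start = win$start,
         rmssd = res[1, ], hrv = res[2, ], rsa = res[3, ], hr = res[4, ],
         n_intervals = as.integer(res[5, ]))
}

#' Per-condition cardiac summary
#'
#' Computes RMSSD, log-variance HRV, band-limited RSA and mean heart rate over
#' a moving window within each condition segment, averages each metric across
#' windows (the epoch mean), and attaches the segment-level respiration peak
#' frequency and its validity flag (`resp_peak >= 0.12` Hz). Windows with
#' fewer than 3 intervals are excluded from the epoch mean with a warning.
#'
#' @param series An IBI tibble covering the whole session.
#' @param segments A segments tibble (`label`, `start`, `end`).
#' @param window_length,window_step Moving-window geometry, s.
#' @param filter Respiratory-band FIR from [design_band_filter()].
#' @param sample_rate Interpolation rate, Hz.
#' @param rmssd_source Compute RMSSD from raw `"intervals"` (the standard
#'   definition) or from the `"interpolated"` series (sensitivity analysis).
#' @return A tibble with one row per condition: `subject_id`, `condition`,
#'   `rmssd`, `hrv`, `rsa`, `hr`, `resp_peak`, `rsa_valid`, `n_windows`.
#' @export
condition_summary <- function(series, segments, window_length = 30,
                              window_step = 3, filter = design_band_filter(),
                              sample_rate = 10,
                              rmssd_source = c("intervals", "interpolated")) {
  rmssd_source <- match.arg(rmssd_source)
  seg <- segment_by_condition(series, segments)
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    lab <- segments$label[i]
    sub <- seg[seg$condition == lab, , drop = FALSE]
    sub$condition <- NULL
    res <- tryCatch(
      segment_window_metrics(sub, segments$start[i], segments$end[i],
                             window_length, window_step, filter, sample_rate,
                             rmssd_source),
      cvcreact_insufficient_data_error = function(e) {
        abort_insufficient(sprintf("condition '%s': %s", lab, conditionMessage(e)))
      }
    )
    ok <- !is.na(res$rmssd)
    if (any(!ok)) {
      warn(sprintf("condition '%s': %d window(s) skipped (fewer than 3 intervals).",
                   lab, sum(!ok)))
    }
    resp <- respiration_peak(interpolate_ibi(sub, sample_rate))
    tibble(
      subject_id = series$subject_id[1],
      condition = lab,
      rmssd = mean(res$rmssd[ok]),
      hrv = if (all(is.na(res$hrv))) NA_real_ else mean(res$hrv, na.rm = TRUE),
      rsa = if (all(is.na(res$rsa))) NA_real_ else mean(res$rsa, na.rm = TRUE),
      hr = mean(res$hr, na.rm = TRUE),
      resp_peak = resp$freq,
      rsa_valid = resp$valid,
      n_windows = sum(ok)
    )
  })
}

#' Summarise every session of a simulated population
#'
#' @param population A `cvc_population` from [simulate_population()].
#' @param ... Passed on to [condition_summary()].
#' @return A tibble of per-subject, per-condition summaries.
#' @export
summarise_population <- function(population, ...) {
  purrr::map_dfr(seq_len(nrow(population$sessions)), function(i) {
    condition_summary(population$sessions$ibi[[i]],
                      population$sessions$segments[[i]], ...)
  })
}

#' Wide reactivity profiles from a per-condition summary
#'
#' @param metrics Output of [condition_summary()] /
#'   [summarise_population()].
#' @param metric Which column to spread (default `"rmssd"`).
#' @return A tibble with `subject_id` and one `<metric>_<condition>` column
#'   per condition.
#' @export
reactivity_profiles <- function(metrics, metric = "rmssd") {
  metrics |>
    select("subject_id", "condition", dplyr::all_of(metric)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = dplyr::all_of(metric),
                       names_prefix = paste0(metric, "_"))
}
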