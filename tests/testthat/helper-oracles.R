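# Independent oracles and small fixtures used across the suite. Each oracle is
# written from the textbook definition, not by calling the package code paths
# it is meant to check.

# Direct-definition RMSSD.
oracle_rmssd <- function(v) sqrt(sum(diff(v)^2) / (length(v) - 1))

# Epoch-mean RMSSD over a moving window, computed by brute force: for each
# window collect the intervals whose two defining beats both fall inside
# [start, start + len) and apply the definition.
oracle_windowed_rmssd <- function(series, len = 30, step = 3,
                                  origin = NULL, end = NULL) {
  t2 <- series$time_s
  t1 <- t2 - series$ibi_ms / 1000
  origin <- origin %||% (t2[1] - series$ibi_ms[1] / 1000)
  end <- end %||% max(t2)
  starts <- seq(origin, end - len, by = step)
  vals <- vapply(starts, function(s) {
    sel <- t1 >= s & t2 < s + len
    if (sum(sel) < 3) return(NA_real_)
    oracle_rmssd(series$ibi_ms[sel])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

# Textbook Spearman coefficient for untied data.
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all rank
# assignments (no ties). U statistic convention of the first group.
oracle_mw_exact <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Variance of a linearly interpolated sinusoid sampled at beat spacing delta:
# between consecutive exact samples the chord replaces the arc, which
# attenuates the A^2/2 continuum value by (2/3) * (1 + cos(2*pi*f*delta) / 2).
oracle_interp_sine_var <- function(amp, freq, delta_s) {
  phi <- 2 * pi * freq * delta_s
  (amp^2 / 2) * (2 / 3) * (1 + cos(phi) / 2)
}

# A regular 10-Hz series holding a pure sinusoid, as a tibble compatible with
# the metric operations.
regular_sine <- function(amp, freq, duration = 300, rate = 10, mean_ms = 800) {
  t <- seq(0, duration, by = 1 / rate)
  out <- tibble::tibble(time_s = t, ibi_ms = mean_ms + amp * sin(2 * pi * freq * t))
  attr(out, "sample_rate") <- rate
  out
}

constant_ibi <- function(n = 400, ibi = 800, subject_id = "s1") {
  ibi_from_intervals(rep(ibi, n), subject_id = subject_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
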