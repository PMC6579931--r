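test_that("interpolation preserves constants and is piecewise linear", {
  s <- constant_ibi(20)
  reg <- interpolate_ibi(s)
  expect_true(all(reg$ibi_ms == 800))
  expect_equal(attr(reg, "sample_rate"), 10)

  # values 800 then 900 at positions 0.9 s apart: midpoint reads 850
  s2 <- ibi_from_intervals(c(800, 900))
  reg2 <- interpolate_ibi(s2, sample_rate = 20)
  mid <- which(abs(reg2$time_s - 1.25) < 1e-9)
  expect_equal(reg2$ibi_ms[mid], 850)

  expect_error(interpolate_ibi(ibi_from_intervals(800)),
               class = "cvcreact_insufficient_data_error")
})

test_that("moving windows follow the 30 s / 3 s epoch geometry", {
  expect_equal(nrow(moving_windows(300)), 91)
  expect_equal(nrow(moving_windows(90)), 21)
  expect_equal(nrow(moving_windows(30)), 1)
  w <- moving_windows(300)
  expect_equal(w$start[1:3], c(0, 3, 6))
  expect_error(moving_windows(29), class = "cvcreact_insufficient_data_error")
  expect_error(moving_windows(300, length = 30, step = 40),
               class = "cvcreact_config_error")
})

test_that("rmssd, mean_hr and ln_variance match their definitions", {
  expect_equal(rmssd(rep(800, 10)), 0)
  expect_equal(rmssd(rep(c(800, 820), 10)), 20)
  expect_equal(rmssd(c(800, 810, 790, 830)), sqrt(700))
  expect_equal(mean_hr(rep(800, 5)), 75)
  expect_equal(mean_hr(rep(1000, 2)), 60)
  expect_equal(mean_hr(c(800, 1200)), 60)

  t <- seq(0, 600, by = 0.1)
  x <- 50 * sin(2 * pi * 0.25 * t)
  expect_equal(ln_variance(x), log(1250), tolerance = 0.005)
  expect_equal(ln_variance(2 * x) - ln_variance(x), log(4), tolerance = 1e-9)
  expect_true(is.na(ln_variance(rep(5, 10))))
})

test_that("scale equivariance: deviations scaled by c shift the metrics accordingly", {
  set.seed(42)
  v <- 800 + rnorm(500, 0, 25)
  for (c_ in c(0.5, 2, 3.7)) {
    v2 <- 800 + c_ * (v - 800)
    expect_equal(rmssd(v2), c_ * rmssd(v), tolerance = 1e-12)
    expect_equal(ln_variance(v2), ln_variance(v) + 2 * log(c_), tolerance = 1e-9)
  }
})

test_that("band-limited RSA matches the closed form in and out of band", {
  h <- design_band_filter()
  in_band <- regular_sine(50, 0.25)
  rsa_in <- ln_variance(apply_band_filter(in_band$ibi_ms, h))
  expect_lt(abs(rsa_in - log(1250)), 0.1)

  out_band <- regular_sine(50, 0.05)
  rsa_out <- ln_variance(apply_band_filter(out_band$ibi_ms, h))
  expect_lte(rsa_out, log(1250) + 2 * log(0.05))

  # a mixture is dominated by its in-band component
  mix <- regular_sine(50, 0.25)
  mix$ibi_ms <- mix$ibi_ms + 60 * sin(2 * pi * 0.05 * mix$time_s)
  rsa_mix <- ln_variance(apply_band_filter(mix$ibi_ms, h))
  expect_lt(abs(exp(rsa_mix) / 1250 - 1), 0.1)
})

test_that("respiration peak finds the dominant IBI-spectrum frequency", {
  fast <- regular_sine(30, 0.25)
  p1 <- respiration_peak(fast)
  expect_lt(abs(p1$freq - 0.25), 0.01)
  expect_true(p1$valid)

  slow <- regular_sine(30, 0.10)
  p2 <- respiration_peak(slow)
  expect_lt(abs(p2$freq - 0.10), 0.01)
  expect_false(p2$valid)

  # the larger-power component wins in a mixture
  mix <- regular_sine(60, 0.10)
  mix$ibi_ms <- mix$ibi_ms + 20 * sin(2 * pi * 0.25 * mix$time_s)
  p3 <- respiration_peak(mix)
  expect_lt(abs(p3$freq - 0.10), 0.01)
  expect_false(p3$valid)

  short <- regular_sine(30, 0.25, duration = 40)
  expect_error(respiration_peak(short),
               class = "cvcreact_insufficient_data_error")
})

test_that("condition summary equals whole-segment metrics on stationary input", {
  sess <- simulate_session(rr_sim_config(seed = 14), withdrawal = 0,
                           responder = FALSE)
  cs <- condition_summary(sess$ibi, sess$segments)
  expect_equal(cs$n_windows, c(91L, 21L, 91L))
  by_cond <- segment_by_condition(sess$ibi, sess$segments)
  for (i in seq_len(3)) {
    whole <- oracle_rmssd(by_cond$ibi_ms[by_cond$condition == cs$condition[i]])
    expect_lt(abs(cs$rmssd[i] / whole - 1), 0.05)
  }
})

test_that("responder sessions show withdrawal and rebound in the summary", {
  sess <- simulate_session(rr_sim_config(seed = 15), withdrawal = 0.5,
                           responder = TRUE)
  cs <- condition_summary(sess$ibi, sess$segments)
  expect_lt(cs$rmssd[cs$condition == "stress"],
            cs$rmssd[cs$condition == "baseline"])
  expect_gt(cs$rmssd[cs$condition == "recovery"],
            cs$rmssd[cs$condition == "stress"])
})

test_that("degenerate constant input yields exact HR, zero RMSSD, NA variance", {
  s <- constant_ibi(900)  # 720 s
  seg <- session_protocol()[, c("label", "start", "end")]
  cs <- suppressWarnings(condition_summary(s, seg))
  expect_true(all(cs$rmssd == 0))
  expect_true(all(cs$hr == 75))
  expect_true(all(is.na(cs$hrv)))
  expect_true(all(is.na(cs$rsa)))
  expect_true(all(!cs$rsa_valid))
})

test_that("epoch RMSSD agrees with the brute-force window oracle", {
  s <- simulate_rr_series(rr_sim_config(duration = 120, seed = 77))
  seg <- tibble::tibble(label = "baseline", start = 0, end = 120)
  cs <- condition_summary(s, seg)
  expect_equal(cs$rmssd,
               oracle_windowed_rmssd(s, origin = 0, end = 120),
               tolerance = 1e-10)
})

test_that("the RSA validity flag equals (respiration peak >= 0.12 Hz)", {
  for (f in c(0.09, 0.3)) {
    cfg <- rr_sim_config(resp_freq = f, resp_amp = 40, lf_amp = 10,
                         noise_sd = 10, duration = 120, seed = 3)
    s <- simulate_rr_series(cfg)
    cs <- condition_summary(s, tibble::tibble(label = "baseline",
                                              start = 0, end = 120))
    expect_equal(cs$rsa_valid, cs$resp_peak >= 0.12)
    expect_equal(cs$rsa_valid, f >= 0.12)
  }
})
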