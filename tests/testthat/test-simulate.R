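test_that("noise-free constant-rate config produces exact intervals", {
  cfg <- rr_sim_config(mean_ibi = 800, resp_amp = 0, lf_amp = 0, noise_sd = 0,
                       duration = 10, seed = 1)
  s <- simulate_rr_series(cfg)
  expect_true(all(s$ibi_ms == 800))
  expect_equal(s$time_s, seq_len(nrow(s)) * 0.8, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical series, different seeds differ", {
  cfg <- rr_sim_config(seed = 33)
  expect_identical(simulate_rr_series(cfg), simulate_rr_series(cfg))
  cfg2 <- rr_sim_config(seed = 34)
  expect_false(identical(simulate_rr_series(cfg)$ibi_ms,
                         simulate_rr_series(cfg2)$ibi_ms))
})

test_that("interpolated variance of sinusoidal modulation matches closed form", {
  # chord interpolation between beat samples attenuates A^2/2 by a known
  # factor; at slow modulation the attenuation is negligible
  for (f in c(0.10, 0.25)) {
    cfg <- rr_sim_config(mean_ibi = 800, resp_freq = f, resp_amp = 50,
                         lf_amp = 0, noise_sd = 0, duration = 300, seed = 2)
    v <- var(interpolate_ibi(simulate_rr_series(cfg))$ibi_ms)
    expect_equal(v, oracle_interp_sine_var(50, f, 0.8), tolerance = 0.05)
  }
  # dense sampling (fast beat rate relative to modulation): A^2/2 within 5%
  cfg <- rr_sim_config(mean_ibi = 400, resp_freq = 0.1, resp_amp = 50,
                       lf_amp = 0, noise_sd = 0, duration = 300, seed = 2)
  v <- var(interpolate_ibi(simulate_rr_series(cfg))$ibi_ms)
  expect_equal(v, 1250, tolerance = 0.05)
})

test_that("invalid simulator configs raise config errors naming the field", {
  expect_error(rr_sim_config(mean_ibi = -5), class = "cvcreact_config_error")
  expect_error(rr_sim_config(resp_freq = 0.9),  # above beat-rate Nyquist
               class = "cvcreact_config_error")
  expect_error(rr_sim_config(noise_sd = -1), regexp = "noise_sd")
  expect_error(rr_sim_config(duration = 0), class = "cvcreact_config_error")
})

test_that("vagal withdrawal lowers stress-segment RMSSD for responders only", {
  cfg <- rr_sim_config(resp_amp = 50, seed = 9)
  resp <- simulate_session(cfg, withdrawal = 0.5, responder = TRUE)
  seg <- resp$segments
  by_cond <- segment_by_condition(resp$ibi, seg)
  r_base <- oracle_rmssd(by_cond$ibi_ms[by_cond$condition == "baseline"])
  r_stress <- oracle_rmssd(by_cond$ibi_ms[by_cond$condition == "stress"])
  r_recov <- oracle_rmssd(by_cond$ibi_ms[by_cond$condition == "recovery"])
  expect_lt(r_stress, 0.8 * r_base)
  expect_gt(r_recov, r_stress)

  # withdrawal = 0 is a no-op: identical series to a non-responder
  same <- simulate_session(cfg, withdrawal = 0, responder = TRUE)
  none <- simulate_session(cfg, withdrawal = 0.7, responder = FALSE)
  expect_identical(same$ibi, none$ibi)
})

test_that("non-responder stress/baseline difference sits inside the null band", {
  # Monte-Carlo null band for the stress-vs-baseline RMSSD ratio when nothing
  # changes across segments
  ratios <- vapply(1:40, function(s) {
    sess <- simulate_session(rr_sim_config(seed = s), withdrawal = 0.6,
                             responder = FALSE)
    bc <- segment_by_condition(sess$ibi, sess$segments)
    oracle_rmssd(bc$ibi_ms[bc$condition == "stress"]) /
      oracle_rmssd(bc$ibi_ms[bc$condition == "baseline"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
  expect_lt(max(abs(ratios - 1)), 0.25)
})

test_that("protocol validation rejects unknown labels", {
  expect_error(
    session_protocol(tibble::tibble(label = c("baseline", "nap"),
                                    duration = c(300, 60))),
    class = "cvcreact_protocol_error"
  )
})

test_that("population generator enforces its invariants and scales", {
  pop <- simulate_population(population_config(n_subjects = 50, seed = 3),
                             protocol = session_protocol(
                               tibble::tibble(label = "baseline", duration = 60)))
  subj <- pop$subjects
  expect_equal(nrow(subj), 50)
  expect_equal(sum(subj$responder), round(0.48 * 50))
  expect_equal(sum(subj$slow_breather), round(0.772 * 50))
  expect_true(all(subj$resp_freq[subj$slow_breather] >= 0.08 &
                    subj$resp_freq[subj$slow_breather] <= 0.11))
  expect_true(all(subj$resp_freq[!subj$slow_breather] >= 0.15 &
                    subj$resp_freq[!subj$slow_breather] <= 0.35))
  expect_true(all(subj$msceit_total > 0))
  expect_error(population_config(n_subjects = 1), class = "cvcreact_config_error")
  expect_error(population_config(rho_ei_cvc = 1.2), class = "cvcreact_config_error")
})

test_that("EI-CVC coupling is recovered from the latent construction", {
  # parameter-recovery Monte Carlo on the generator's own latents: the
  # acceptance suite repeats this through the full windowed-metric path
  recovered <- vapply(1:30, function(s) {
    pop <- simulate_population(
      population_config(n_subjects = 100, rho_ei_cvc = 0.3, seed = s),
      protocol = session_protocol(tibble::tibble(label = "baseline",
                                                 duration = 30)))
    cor(pop$subjects$msceit_total, pop$subjects$lrmssd_latent)
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 0.3), 0.05)
})

test_that("null coupling yields near-zero Spearman correlation on average", {
  recovered <- vapply(1:30, function(s) {
    pop <- simulate_population(
      population_config(n_subjects = 100, rho_ei_cvc = 0, seed = s),
      protocol = session_protocol(tibble::tibble(label = "baseline",
                                                 duration = 30)))
    cor(pop$subjects$msceit_total, pop$subjects$lrmssd_latent,
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(recovered)), 0.03)
})

test_that("artifact injection conserves elapsed time and keeps a ledger", {
  s <- simulate_rr_series(rr_sim_config(seed = 11))
  out <- inject_artifacts(s, artifact_config(p_missed = 0.05, p_extra = 0.05,
                                             p_ectopic = 0.05, seed = 4))
  led <- artifact_ledger(out)
  expect_gt(nrow(led), 0)
  expect_true(all(led$type %in% c("missed", "extra", "ectopic")))
  expect_lt(abs(sum(out$ibi_ms) - sum(s$ibi_ms)), mean(s$ibi_ms))
  expect_true(all(out$ibi_ms > 0))

  # zero probabilities are a no-op
  expect_identical(
    inject_artifacts(s, artifact_config(0, 0, 0, seed = 1))$ibi_ms, s$ibi_ms)

  # a missed beat merges two adjacent intervals: on a constant series the
  # merged interval is exactly the pairwise sum, and elapsed time is conserved
  const <- constant_ibi(60)
  merged <- inject_artifacts(const, artifact_config(p_missed = 0.2, p_extra = 0,
                                                    p_ectopic = 0, seed = 2))
  led2 <- artifact_ledger(merged)
  expect_gt(nrow(led2), 0)
  expect_true(all(merged$ibi_ms[led2$index] == 1600))
  expect_equal(sum(merged$ibi_ms), sum(const$ibi_ms))
  expect_error(artifact_config(p_missed = 0.5), class = "cvcreact_config_error")
})

test_that("summary-level profile generator mirrors the session model", {
  prof <- simulate_reactivity_profiles(200, withdrawal = 0.5,
                                       responder_fraction = 0.5, seed = 8)
  expect_equal(sum(prof$responder), 100)
  by_grp <- split(prof, prof$responder)
  ratio_resp <- mean(by_grp$`TRUE`$rmssd_stress / by_grp$`TRUE`$rmssd_baseline)
  ratio_non <- mean(by_grp$`FALSE`$rmssd_stress / by_grp$`FALSE`$rmssd_baseline)
  expect_equal(ratio_resp, sqrt(0.02 + 0.98 * 0.25), tolerance = 0.1)
  expect_equal(ratio_non, 1, tolerance = 0.1)
  expect_identical(prof, simulate_reactivity_profiles(200, withdrawal = 0.5,
                                                      responder_fraction = 0.5,
                                                      seed = 8))
})

test_that("three-group mixture fixture has the intended group structure", {
  prof <- simulate_profile_mixture(n = 102, seed = 5)
  expect_equal(table(prof$group)[["low"]], 53)
  means <- tapply(prof$rmssd_baseline, prof$group, mean)
  expect_equal(as.numeric(means[c("low", "mid", "high")]),
               c(19.76, 39.69, 73.44), tolerance = 0.1)
  expect_true(all(prof$responder == (prof$group != "low")))
})
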