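#' Configuration for a simulated RR-interval series
#'
#' The simulator writes each interval as a mean level plus a respiratory
#' sinusoid, a low-frequency (~0.1 Hz, baroreflex-band) sinusoid with a
#' seed-drawn phase, and white beat-to-beat noise. Defaults describe a resting
#' adult with heart rate near 85 bpm and RMSSD near 33 ms.
#'
#' @param mean_ibi Mean interbeat interval, ms.
#' @param resp_freq Respiratory modulation frequency, Hz. Must stay below the
#'   beat-rate Nyquist `0.5 * 1000 / mean_ibi`.
#' @param resp_amp Peak amplitude of respiratory IBI modulation, ms.
#' @param lf_freq,lf_amp Frequency (Hz) and peak amplitude (ms) of the
#'   low-frequency oscillation.
#' @param noise_sd SD of white noise added per beat, ms.
#' @param duration Recording length, s.
#' @param seed Integer seed; identical seeds give bit-identical series.
#' @return A validated `rr_sim_config` list.
#' @export
rr_sim_config <- function(mean_ibi = 709, resp_freq = 0.25, resp_amp = 22,
                          lf_freq = 0.1, lf_amp = 10.5, noise_sd = 20,
                          duration = 300, seed = 1L) {
  check_number(mean_ibi, "mean_ibi", min = 0, strict_min = TRUE)
  check_number(resp_freq, "resp_freq", min = 0, max = 0.5 * 1000 / mean_ibi,
               strict_min = TRUE, strict_max = TRUE)
  check_number(resp_amp, "resp_amp", min = 0)
  check_number(lf_freq, "lf_freq", min = 0, strict_min = TRUE)
  check_number(lf_amp, "lf_amp", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(duration, "duration", min = 0, strict_min = TRUE)
  check_number(seed, "seed")
  structure(
    list(mean_ibi = mean_ibi, resp_freq = resp_freq, resp_amp = resp_amp,
         lf_freq = lf_freq, lf_amp = lf_amp, noise_sd = noise_sd,
         duration = duration, seed = as.integer(seed)),
    class = "rr_sim_config"
  )
}

#' Protocol of labelled condition segments
#'
#' @param segments A data frame with columns `label` (baseline, stress,
#'   recovery) and `duration` (s). The default is the reactivity protocol of a
#'   5-minute rest, a 90-s serial-subtraction stressor, and a 5-minute
#'   recovery rest.
#' @return A tibble with columns `label`, `duration`, `start`, `end`.
#' @export
session_protocol <- function(segments = tibble(
  label = c("baseline", "stress", "recovery"),
  duration = c(300, 90, 300)
)) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0L) abort_config("protocol must have at least one segment.")
  if (!all(c("label", "duration") %in% names(segments))) {
    abort_config("protocol needs columns label and duration.")
  }
  if (!all(segments$label %in% .cvc_conditions)) {
    abort(sprintf("unknown segment label(s): %s.",
                  paste(setdiff(segments$label, .cvc_conditions), collapse = ", ")),
          class = "cvcreact_protocol_error")
  }
  if (any(segments$duration <= 0)) abort_config("segment durations must be positive.")
  segments$end <- cumsum(segments$duration)
  segments$start <- segments$end - segments$duration
  segments[, c("label", "duration", "start", "end")]
}

#' Simulate an RR-interval series
#'
#' @param config An [rr_sim_config()].
#' @return An IBI tibble (see [ibi_from_intervals()]).
#' @examples
#' head(simulate_rr_series(rr_sim_config(noise_sd = 0, seed = 7)))
#' @export
simulate_rr_series <- function(config) {
  if (!inherits(config, "rr_sim_config")) config <- do.call(rr_sim_config, config)
  sim <- withr::with_seed(config$seed, {
    phase <- runif(1, 0, 2 * pi)
    .rr_recurrence(config$mean_ibi, config$resp_freq, config$lf_freq, phase,
                   config$duration, config$resp_amp, config$lf_amp,
                   config$noise_sd)
  })
  out <- tibble(
    subject_id = "s1",
    time_s = sim$beat_times[-1],
    ibi_ms = sim$ibi_ms,
    flag = "clean"
  )
  attr(out, "source") <- "simulate_rr_series"
  out
}

#' Subject-level simulator configuration from physiological targets
#'
#' Converts a subject's breathing frequency, target RMSSD and mean heart rate
#' into component amplitudes using the generator's fixed spectral shares of
#' squared RMSSD (respiratory sinusoid, low-frequency sinusoid, beat noise).
#' This is the rule [simulate_population()] applies to every subject.
#'
#' @param resp_freq Breathing frequency, Hz.
#' @param target_rmssd Target RMSSD, ms.
#' @param mean_hr Mean heart rate, bpm.
#' @param duration Recording length, s.
#' @param seed Integer seed.
#' @return An [rr_sim_config()].
#' @export
rr_subject_config <- function(resp_freq = 0.25, target_rmssd = 32.74,
                              mean_hr = 84.63, duration = 300, seed = 1L) {
  mean_ibi <- 60000 / mean_hr
  delta <- mean_ibi / 1000
  lf_freq <- 0.1
  rr_sim_config(
    mean_ibi = mean_ibi,
    resp_freq = resp_freq,
    resp_amp = target_rmssd * sqrt(.cvc_shares[["resp"]] / 2) /
      sin(pi * resp_freq * delta),
    lf_freq = lf_freq,
    lf_amp = target_rmssd * sqrt(.cvc_shares[["lf"]] / 2) /
      sin(pi * lf_freq * delta),
    noise_sd = target_rmssd * sqrt(.cvc_shares[["noise"]] / 2),
    duration = duration,
    seed = seed
  )
}

# Map a latent Gaussian coupling variable onto the three-component log-RMSSD
# mixture by rank: the bottom (1 - fraction) of subjects (by z) form the low,
# non-responsive phenotype; responders split between the mid and high
# phenotypes. Rank quantiles keep the marginal exact and group counts fixed.
mixture_lrmssd <- function(z, fraction) {
  n <- length(z)
  r <- rank(z, ties.method = "first")
  n_resp <- round(fraction * n)
  n_high <- round(.cvc_rmssd_mix$high_share * n_resp)
  n_mid <- n_resp - n_high
  n_low <- n - n_resp
  group <- ifelse(r <= n_low, "low", ifelse(r <= n_low + n_mid, "mid", "high"))
  offset <- c(low = 0L, mid = n_low, high = n_low + n_mid)[group]
  size <- c(low = n_low, mid = n_mid, high = n_high)[group]
  u <- (r - offset - 0.5) / pmax(size, 1L)
  mu <- vapply(.cvc_rmssd_mix[group], `[[`, numeric(1), "mu")
  sigma <- vapply(.cvc_rmssd_mix[group], `[[`, numeric(1), "sigma")
  list(level = mu + sigma * qnorm(u), responder = group != "low",
       group = group)
}

# RMSSD multiplier produced by scaling the vagally mediated components
# (respiratory sinusoid and beat noise) by (1 - withdrawal); the low-frequency
# share q_lf is untouched.
withdrawal_factor <- function(withdrawal) {
  q_lf <- .cvc_shares[["lf"]]
  sqrt(q_lf + (1 - q_lf) * (1 - withdrawal)^2)
}

#' Simulate a baseline-stress-recovery session
#'
#' During stress segments of a responder, the vagally mediated components of
#' interbeat variability (the respiratory amplitude and the beat-to-beat
#' noise) are scaled by `1 - withdrawal` and restored in recovery;
#' non-responders keep their baseline dynamics throughout.
#'
#' @inheritParams simulate_rr_series
#' @param protocol A [session_protocol()].
#' @param withdrawal Fraction in `[0, 1]` by which vagal variability is
#'   reduced during stress.
#' @param responder Logical; does this subject react to the stressor?
#' @param subject_id Identifier attached to the series.
#' @return A list of class `cvc_session` with elements `ibi` (IBI tibble) and
#'   `segments` (tibble with `label`, `start`, `end`).
#' @export
simulate_session <- function(config, protocol = session_protocol(),
                             withdrawal = 0, responder = TRUE,
                             subject_id = "s1") {
  if (!inherits(config, "rr_sim_config")) config <- do.call(rr_sim_config, config)
  check_number(withdrawal, "withdrawal", min = 0, max = 1)
  protocol <- session_protocol(protocol[, c("label", "duration")])
  scale <- ifelse(protocol$label == "stress" & isTRUE(responder),
                  1 - withdrawal, 1)
  sim <- withr::with_seed(config$seed, {
    phase <- runif(1, 0, 2 * pi)
    .rr_recurrence(config$mean_ibi, config$resp_freq, config$lf_freq, phase,
                   protocol$end, config$resp_amp * scale,
                   rep(config$lf_amp, nrow(protocol)),
                   config$noise_sd * scale)
  })
  ibi <- tibble(
    subject_id = as.character(subject_id),
    time_s = sim$beat_times[-1],
    ibi_ms = sim$ibi_ms,
    flag = "clean"
  )
  attr(ibi, "source") <- "simulate_session"
  structure(
    list(ibi = ibi,
         segments = protocol[, c("label", "start", "end")]),
    class = "cvc_session"
  )
}

#' Configuration for a simulated subject population
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param ei_mean,ei_sd Mean and SD of the latent emotional-intelligence
#'   trait, standard-score units.
#' @param rho_ei_cvc Correlation between the latent ability-EI trait and the
#'   natural log of baseline RMSSD (imposed through a Gaussian copula on the
#'   log scale).
#' @param stress_withdrawal Fraction in `[0, 1]` by which responders' vagal
#'   variability is reduced during stress.
#' @param responder_fraction Fraction of subjects that react to the stressor.
#'   Responder status is coupled to resting vagal tone: the subjects with the
#'   highest latent baseline RMSSD are the responders, mirroring the observed
#'   association between resting CVC and reactivity.
#' @param slow_breather_fraction Fraction of subjects whose respiration rate
#'   sits below the 0.12 Hz validity floor (drawn from 0.08-0.11 Hz; the rest
#'   breathe at 0.15-0.35 Hz).
#' @param seed Integer master seed; per-subject streams are derived with
#'   [derive_seed()] so subjects are reproducible independently of order.
#' @return A validated `population_config` list.
#' @export
population_config <- function(n_subjects = 102, ei_mean = 100, ei_sd = 15,
                              rho_ei_cvc = 0.2, stress_withdrawal = 0.30,
                              responder_fraction = 0.48,
                              slow_breather_fraction = 0.772, seed = 1L) {
  check_number(n_subjects, "n_subjects", min = 2)
  check_number(ei_mean, "ei_mean", min = 0, strict_min = TRUE)
  check_number(ei_sd, "ei_sd", min = 0, strict_min = TRUE)
  check_number(rho_ei_cvc, "rho_ei_cvc", min = -1, max = 1)
  check_number(stress_withdrawal, "stress_withdrawal", min = 0, max = 1)
  check_number(responder_fraction, "responder_fraction", min = 0, max = 1)
  check_number(slow_breather_fraction, "slow_breather_fraction", min = 0, max = 1)
  check_number(seed, "seed")
  structure(
    list(n_subjects = as.integer(n_subjects), ei_mean = ei_mean, ei_sd = ei_sd,
         rho_ei_cvc = rho_ei_cvc, stress_withdrawal = stress_withdrawal,
         responder_fraction = responder_fraction,
         slow_breather_fraction = slow_breather_fraction,
         seed = as.integer(seed)),
    class = "population_config"
  )
}

#' Simulate a study population
#'
#' Draws a latent EI trait and a latent log baseline RMSSD from a bivariate
#' normal with correlation `rho_ei_cvc`, converts each subject's target RMSSD
#' into respiratory, low-frequency, and noise amplitudes using the package's
#' fixed spectral shares, and simulates one session per subject under the
#' given protocol. EI questionnaire scores (ability total plus four branches;
#' mixed total plus five composites) and demographic covariates are generated
#' around the latent traits; covariates do not feed back into physiology.
#'
#' @param pop A [population_config()].
#' @param protocol A [session_protocol()] used for every subject.
#' @return A list of class `cvc_population` with elements `subjects` (one row
#'   per subject) and `sessions` (tibble with list-columns `ibi`, `segments`).
#' @export
simulate_population <- function(pop = population_config(),
                                protocol = session_protocol()) {
  if (!inherits(pop, "population_config")) pop <- do.call(population_config, pop)
  n <- pop$n_subjects
  draws <- withr::with_seed(pop$seed, {
    z_ei <- rnorm(n)
    z_c <- pop$rho_ei_cvc * z_ei + sqrt(1 - pop$rho_ei_cvc^2) * rnorm(n)
    z_eq <- 0.25 * z_ei + sqrt(1 - 0.25^2) * rnorm(n)
    hr <- pmin(pmax(rnorm(n, .cvc_hr[["mean"]], .cvc_hr[["sd"]]), 55), 120)
    slow <- rep(FALSE, n)
    n_slow <- round(pop$slow_breather_fraction * n)
    if (n_slow > 0) slow[sample.int(n, n_slow)] <- TRUE
    resp_freq <- ifelse(slow, runif(n, 0.08, 0.11), runif(n, 0.15, 0.35))
    branch <- function(z) pop$ei_mean + pop$ei_sd * (0.75 * z + sqrt(1 - 0.75^2) * rnorm(n))
    list(
      z_ei = z_ei, z_c = z_c, hr = hr, slow = slow, resp_freq = resp_freq,
      msceit_total = pop$ei_mean + pop$ei_sd * z_ei,
      msceit_perceiving = branch(z_ei), msceit_using = branch(z_ei),
      msceit_understanding = branch(z_ei), msceit_managing = branch(z_ei),
      eqi_total = pop$ei_mean + pop$ei_sd * z_eq,
      eqi_self_perception = branch(z_eq), eqi_self_expression = branch(z_eq),
      eqi_interpersonal = branch(z_eq), eqi_decision_making = branch(z_eq),
      eqi_stress_management = branch(z_eq),
      age = round(pmin(pmax(rnorm(n, 22.8, 4.4), 18), 40), 1),
      gender = sample(c("female", "male"), n, replace = TRUE, prob = c(0.63, 0.37)),
      caffeine = sample(c("no", "yes"), n, replace = TRUE, prob = c(0.6, 0.4)),
      time_of_day = round(runif(n, 8, 18), 2)
    )
  })
  mix <- mixture_lrmssd(draws$z_c, pop$responder_fraction)
  target_lrmssd <- mix$level
  responder <- mix$responder
  target <- exp(target_lrmssd)

  ids <- sprintf("s%03d", seq_len(n))
  subjects <- tibble(
    subject_id = ids,
    age = draws$age, gender = draws$gender, caffeine = draws$caffeine,
    time_of_day = draws$time_of_day,
    msceit_total = draws$msceit_total,
    msceit_perceiving = draws$msceit_perceiving,
    msceit_using = draws$msceit_using,
    msceit_understanding = draws$msceit_understanding,
    msceit_managing = draws$msceit_managing,
    eqi_total = draws$eqi_total,
    eqi_self_perception = draws$eqi_self_perception,
    eqi_self_expression = draws$eqi_self_expression,
    eqi_interpersonal = draws$eqi_interpersonal,
    eqi_decision_making = draws$eqi_decision_making,
    eqi_stress_management = draws$eqi_stress_management,
    responder = responder, group = mix$group, slow_breather = draws$slow,
    resp_freq = draws$resp_freq, lrmssd_latent = target_lrmssd
  )

  duration <- sum(protocol$duration)
  sessions <- purrr::map(seq_len(n), function(i) {
    cfg <- rr_subject_config(
      resp_freq = draws$resp_freq[i], target_rmssd = target[i],
      mean_hr = draws$hr[i], duration = duration,
      seed = derive_seed(pop$seed, i)
    )
    simulate_session(cfg, protocol, withdrawal = pop$stress_withdrawal,
                     responder = responder[i], subject_id = ids[i])
  })
  structure(
    list(
      subjects = subjects,
      sessions = tibble(
        subject_id = ids,
        ibi = purrr::map(sessions, "ibi"),
        segments = purrr::map(sessions, "segments")
      ),
      config = pop
    ),
    class = "cvc_population"
  )
}

#' Simulate per-condition RMSSD reactivity profiles
#'
#' A summary-level companion to [simulate_population()]: instead of producing
#' beat series it draws each subject's per-condition RMSSD directly from the
#' same population model (lognormal between-subject spread, within-subject
#' log-scale measurement noise, and a stress-condition reduction of
#' `withdrawal_factor()` for responders). Useful when only the statistical
#' stages are under study.
#'
#' @param n Number of subjects.
#' @param withdrawal Vagal withdrawal fraction for responders during stress.
#' @param responder_fraction Fraction of responders; as in
#'   [simulate_population()], responders draw their baseline level from the
#'   upper component of the latent RMSSD mixture.
#' @param sd_within SD of within-subject log-scale fluctuation per condition
#'   (day-level physiological state beyond the stationary beat model).
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `responder`, `rmssd_baseline`,
#'   `rmssd_stress`, `rmssd_recovery`.
#' @export
simulate_reactivity_profiles <- function(n, withdrawal = 0.30,
                                         responder_fraction = 0.48,
                                         sd_within = 0.15, seed = 1L) {
  check_number(n, "n", min = 2)
  check_number(withdrawal, "withdrawal", min = 0, max = 1)
  check_number(responder_fraction, "responder_fraction", min = 0, max = 1)
  withr::with_seed(seed, {
    mix <- mixture_lrmssd(rnorm(n), responder_fraction)
    lb <- mix$level
    responder <- mix$responder
    shift <- ifelse(responder, log(withdrawal_factor(withdrawal)), 0)
    tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      responder = responder,
      group = mix$group,
      rmssd_baseline = exp(lb + sd_within * rnorm(n)),
      rmssd_stress = exp(lb + shift + sd_within * rnorm(n)),
      rmssd_recovery = exp(lb + sd_within * rnorm(n))
    )
  })
}

#' Simulate a three-group reactivity-profile mixture
#'
#' Draws per-condition RMSSD profiles from three lognormal blobs mirroring the
#' low/mid/high CVC reactivity phenotypes (flat low group; mid and high groups
#' with vagal withdrawal under stress and rebound in recovery). With the
#' default coefficients of variation the groups are well separated, which
#' makes this the reference fixture for cluster-recovery checks.
#'
#' @param n Number of subjects.
#' @param weights Mixture weights for the low/mid/high groups.
#' @param means 3 x 3 matrix of group-by-condition RMSSD means (ms); rows
#'   low/mid/high, columns baseline/stress/recovery.
#' @param cv_subject Coefficient of variation of the shared subject level.
#' @param cv_within Additional per-condition coefficient of variation.
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `group`, `responder`, and the three
#'   `rmssd_*` columns.
#' @export
simulate_profile_mixture <- function(n = 102,
                                     weights = c(low = 0.52, mid = 0.38,
                                                 high = 0.10),
                                     means = matrix(
                                       c(19.76, 20.03, 20.79,
                                         39.69, 29.49, 41.42,
                                         73.44, 51.51, 70.36),
                                       nrow = 3, byrow = TRUE,
                                       dimnames = list(
                                         c("low", "mid", "high"),
                                         .cvc_conditions)),
                                     cv_subject = 0.08, cv_within = 0.03,
                                     seed = 1L) {
  check_number(n, "n", min = 3)
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0) {
    abort_config("`weights` must be three non-negative numbers.", "weights")
  }
  weights <- weights / sum(weights)
  withr::with_seed(seed, {
    counts <- diff(round(cumsum(c(0, weights)) * n))
    group <- rep(c("low", "mid", "high"), counts)
    subj <- exp(rnorm(n, 0, sqrt(log(1 + cv_subject^2))))
    eps <- matrix(exp(rnorm(3 * n, 0, sqrt(log(1 + cv_within^2)))), n, 3)
    prof <- means[group, , drop = FALSE] * subj * eps
    tibble(
      subject_id = sprintf("s%03d", seq_len(n)),
      group = group,
      responder = group != "low",
      rmssd_baseline = prof[, 1],
      rmssd_stress = prof[, 2],
      rmssd_recovery = prof[, 3]
    )
  })
}

#' Configuration for beat-artifact injection
#'
#' @param p_missed,p_extra,p_ectopic Per-beat probabilities (each in
#'   `[0, 0.2]`) of merging two adjacent intervals (a missed beat), splitting
#'   one interval (an extra detection), or perturbing a beat time by 20-40% of
#'   its interval (an ectopic beat).
#' @param seed Integer seed.
#' @return A validated `artifact_config` list.
#' @export
artifact_config <- function(p_missed = 0.01, p_extra = 0.01, p_ectopic = 0.02,
                            seed = 1L) {
  check_number(p_missed, "p_missed", min = 0, max = 0.2)
  check_number(p_extra, "p_extra", min = 0, max = 0.2)
  check_number(p_ectopic, "p_ectopic", min = 0, max = 0.2)
  check_number(seed, "seed")
  structure(
    list(p_missed = p_missed, p_extra = p_extra, p_ectopic = p_ectopic,
         seed = as.integer(seed)),
    class = "artifact_config"
  )
}

#' Inject beat artifacts into an IBI series
#'
#' Events are sampled per interval and applied so that total elapsed time is
#' conserved exactly: a missed beat merges two adjacent intervals, an extra
#' beat splits one interval at a 40-60% point, and an ectopic beat moves one
#' beat by 20-40% of its interval (shortening one interval and lengthening its
#' neighbour). A ledger of injected events, indexed against the *output*
#' series, is attached as attribute `"artifact_ledger"`.
#'
#' @param series An IBI tibble with at least 3 beats.
#' @param cfg An [artifact_config()].
#' @return The corrupted IBI tibble with an `"artifact_ledger"` attribute.
#' @export
inject_artifacts <- function(series, cfg = artifact_config()) {
  if (!inherits(cfg, "artifact_config")) cfg <- do.call(artifact_config, cfg)
  validate_ibi(series)
  n <- nrow(series)
  if (n < 2L) abort_insufficient("need at least 3 beats to inject artifacts.")
  v <- series$ibi_ms
  events <- withr::with_seed(cfg$seed, {
    type <- rep("none", n)
    u <- runif(n)
    type[u < cfg$p_missed] <- "missed"
    type[u >= cfg$p_missed & u < cfg$p_missed + cfg$p_extra] <- "extra"
    type[u >= cfg$p_missed + cfg$p_extra &
         u < cfg$p_missed + cfg$p_extra + cfg$p_ectopic] <- "ectopic"
    # events touching index i+1 need a partner interval; enforce gaps >= 2 so
    # injected artifacts do not interact
    last_used <- -2L
    for (i in seq_len(n)) {
      if (type[i] == "none") next
      span <- if (type[i] == "extra") i else i + 1L
      if (i - last_used < 2L || span > n) type[i] <- "none" else last_used <- span
    }
    splits <- runif(n, 0.4, 0.6)
    mags <- runif(n, 0.2, 0.4) * sample(c(-1, 1), n, replace = TRUE)
    list(type = type, splits = splits, mags = mags)
  })
  if (all(events$type == "none")) {
    attr(series, "artifact_ledger") <-
      tibble(type = character(), index = integer(), magnitude = numeric())
    return(series)
  }
  out <- numeric(0)
  led_type <- character(0); led_idx <- integer(0); led_mag <- numeric(0)
  i <- 1L
  while (i <= n) {
    ty <- events$type[i]
    if (ty == "missed") {
      out <- c(out, v[i] + v[i + 1L])
      led_type <- c(led_type, "missed"); led_idx <- c(led_idx, length(out))
      led_mag <- c(led_mag, NA_real_)
      i <- i + 2L
    } else if (ty == "extra") {
      u <- events$splits[i]
      out <- c(out, v[i] * u, v[i] * (1 - u))
      led_type <- c(led_type, "extra"); led_idx <- c(led_idx, length(out) - 1L)
      led_mag <- c(led_mag, u)
      i <- i + 1L
    } else if (ty == "ectopic") {
      d <- events$mags[i] * v[i]
      if (v[i] + d <= 1 || v[i + 1L] - d <= 1) d <- -d
      out <- c(out, v[i] + d, v[i + 1L] - d)
      led_type <- c(led_type, "ectopic"); led_idx <- c(led_idx, length(out) - 1L)
      led_mag <- c(led_mag, abs(d) / v[i])
      i <- i + 2L
    } else {
      out <- c(out, v[i])
      i <- i + 1L
    }
  }
  res <- rebuild_ibi(out, ibi_beat_times(series)[1], series$subject_id[1])
  attr(res, "source") <- attr(series, "source")
  attr(res, "artifact_ledger") <- tibble(type = led_type, index = led_idx,
                                         magnitude = led_mag)
  res
}

#' @rdname inject_artifacts
#' @param x An IBI tibble returned by `inject_artifacts()`.
#' @export
artifact_ledger <- function(x) {
  attr(x, "artifact_ledger") %||%
    tibble(type = character(), index = integer(), magnitude = numeric())
}
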