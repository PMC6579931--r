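---
title: "Models and methods behind cvcreact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cvcreact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvcreact` quantifies cardiac vagal control (CVC) from interbeat-interval
(IBI) series recorded across a baseline–stressor–recovery protocol, relates
resting and reactive CVC to trait scores, and classifies subjects by their
reactivity profile. This vignette documents the models, the tunable
parameters and their defaults, the synthetic-data generator that stands in
for human recordings, and the numerical and design decisions a user should
know before trusting (or extending) the results.

## The measurement model

An IBI series is the sequence of times between successive heartbeats. Vagal
(parasympathetic) influence expresses itself as beat-to-beat variability,
especially at respiratory frequencies (respiratory sinus arrhythmia, RSA).
Four indices are computed on a 30-s moving window advancing 3 s at a time
(`window_length`, `window_step`; seconds). The moving window keeps variance
estimates of a non-stationary series from growing with recording length; the
mean across windows ("epoch mean") is the condition-level value.

* **RMSSD** (ms): `sqrt(mean(diff(ibi)^2))` over the intervals whose two
  defining beats both fall in the window (at least 3 intervals, otherwise
  the window is skipped and counted). Computed on the raw intervals by
  default; `rmssd_source = "interpolated"` switches to the resampled series
  for sensitivity analysis, since the field's definition ("successive
  differences in the IBI time series") is ambiguous about the time base.
* **HRV** (ln ms²): natural log of the variance of the IBI series linearly
  interpolated to a uniform 10-Hz grid (`sample_rate`). Interval values are
  positioned at their *second* beat's time. Variance uses the N denominator
  (population variance), consistent with treating the window as the complete
  signal segment; at 300 samples per window the difference from N−1 is under
  0.4%.
* **RSA** (ln ms²): the same after band-pass filtering with a 241-tap
  linear-phase FIR whose **half-amplitude** frequencies are 0.12 and
  0.40 Hz. The filter is a Hamming-windowed ideal band-pass; the windowed
  construction places ~0.5 gain at the design cut-offs by itself, and
  `design_band_filter()` verifies the realized response (0.5 ± 0.02 at both
  edges, ≥ 0.99 at 0.26 Hz, ≤ 0.05 at 0.05/0.48 Hz) and refuses designs the
  tap count cannot support. Filtering is applied once per condition segment
  after symmetric-reflection padding of half the filter length per side, so
  no window is lost to warm-up and edge variance is not inflated. Any
  linear-phase design meeting the half-amplitude contract is considered
  conformant; the contract, not the design algorithm, is normative.
* **HR** (bpm): 60000 / mean interval.

**Respiration validity.** RSA is only interpretable when the subject
breathes inside the analysis band. The dominant frequency of the
linearly-detrended, Hann-windowed, zero-padded IBI spectrum is located
within 0.05–0.5 Hz; the periodogram is averaged over roughly four resolution
bins first, because the cross term between a spectral line and broadband
noise fluctuates by twice their geometric-mean amplitude and can otherwise
flip the ordering of nearby peaks. A condition's RSA is flagged invalid when
the peak falls below 0.12 Hz. Windows need at least 60 s of data for the
0.05-Hz end of the search band to be resolvable.

**Condition segmentation** uses half-open `[start, end)` windows; an
interval belongs to the segment containing its second beat. The window grid
restarts at each segment's start, so no window straddles conditions (the
analysis reports per-condition means). A tolerance of 1.5 median intervals
is allowed at the recording tail, since a recording necessarily ends at its
last detected beat.

## Artifact handling

Recorded IBI series contain missed beats (two intervals merged), spurious
detections (one interval split), and ectopic beats (one beat time moved,
deflecting the two adjacent intervals in opposite directions). Manual
correction is the field's tradition; `cvcreact` replaces it with a
deterministic, testable procedure.

*Detection* (`detect_artifacts()`): each interval is compared with a
9-interval running median `m`. Intervals above `long_factor * m` (default
1.8) are missed beats; below `short_factor * m` (default 0.5) extra beats;
and an interval is ectopic/erroneous when its relative deviation score
exceeds `rel_threshold` (default 0.25), where the score combines the
deviation from `m` with the adjacent successive differences (the jump
between the two intervals deflected by an ectopic beat is twice the beat
displacement, which lifts even small ectopics far above the
successive-difference noise floor). Differences involving missed/extra
intervals are masked so their clean neighbours are not dragged in.

*Correction* (`correct_artifacts()`): every run of consecutive flagged
intervals is replaced under one conservation rule — the run's elapsed time
divided by the local median says how many true beats it spans, so the run
becomes `k = round(sum/m)` intervals shaped by a cubic spline through the
surrounding clean intervals and rescaled to preserve the run's elapsed time
exactly. This merges split pairs (`k = 1`), re-inserts missed beats
(`k = 2`), and redistributes ectopic pairs (`k = 2`); a run is first
extended by one clean neighbour when that better completes a whole number of
median beats (the half-detected ectopic pair). Records with more than 20% of
intervals flagged are rejected as unusable rather than repaired — mirroring
the practice of excluding unusable recordings when no quantitative criterion
is stated.

On simulated corruption at a 5% total artifact rate, inject-then-correct
epoch RMSSD stays within 10% of the clean reference; the residual error is
dominated by the spline's lack of the (unrecoverable) beat-noise component
inside corrected stretches.

## The statistical battery

All stages use two-tailed α = 0.05 and listwise deletion within each
analysis.

* **Zero-order associations**: pairwise-complete Spearman correlations with
  two-sided p from the t approximation and Bonferroni correction over all
  unique pairs tested.
* **Baseline regressions**: OLS of log outcome on log predictor (both must
  be positive), with the predictor's F test, partial
  η² = SS_effect/(SS_effect + SS_error) — which for a single predictor
  equals the squared correlation of the transformed variables — and residual
  diagnostics (skewness, kurtosis, Shapiro–Wilk, Breusch–Pagan), since log
  transformation is motivated by failed normality/heteroscedasticity checks
  on the raw scale.
* **Subscale selection**: bidirectional stepwise regression minimising AIC
  from the intercept-only model (`MASS::stepAIC`), with deterministic
  tie-breaking by candidate order; an empty selection returns the
  intercept-only model rather than an error.
* **Repeated measures**: generalized least squares with homogeneous residual
  variance and an *unstructured* within-subject correlation among the three
  conditions, estimated by REML (`nlme::gls` with `corSymm`). This is the
  most literal reading of "fixed variances and separate covariances";
  heterogeneous variances and compound symmetry are exposed as options for
  sensitivity analysis, and compound symmetry is the automatic fallback if
  the unstructured fit fails. The package models `log(rmssd)` by default in
  its own analyses, consistent with the log transforms used elsewhere.
* **Model comparison**: `compare_models()` reports ΔAIC and, for nested
  models, the likelihood ratio `2·(ℓ_complex − ℓ_simple)` with a χ² p-value
  on the parameter-count difference. REML likelihoods are not comparable
  across fixed-effect structures, so GLS fits are refit by ML before
  comparison — a statistical necessity rather than a convention choice.
* **Covariate screening**: LASSO of baseline RMSSD on gender, age, caffeine,
  and time of day, dummy-coded and standardized, with the penalty chosen by
  seeded 10-fold cross-validation at the one-standard-error rule. The 1-SE
  rule and fixed fold seed are choices made for reproducibility; the
  unpenalized minimum is available via `rule = "min"`.

Monte-Carlo checks in the test suite verify that the regression F test and
the GLS condition test hold their nominal size (5% ± 1.5% and ± 2%), that
stepwise and LASSO selection recover planted signals in ≥ 95% of replicates
while staying sparse under the null, and that the null likelihood-ratio
statistic matches its χ² reference.

## Responder classification

Per-subject profiles (baseline, stress, recovery RMSSD) are analysed by
correlation-matrix PCA **on the log scale**: RMSSD is approximately
lognormal across subjects and vagal withdrawal is multiplicative, so log
profiles make reactivity additive and comparable across resting levels. Two
components are retained (they carry ≈ 99% of profile variance; the first is
resting level, the second the stress contrast). Ward (`ward.D2`)
agglomerative clustering runs on the retained scores standardized to unit
variance — Mahalanobis geometry — because the resting-level component
otherwise dominates Euclidean distances and masks the reactivity contrast;
raw-scale, unstandardized, and single/complete-linkage variants remain
available as arguments. The dendrogram is cut at k = 3 (configurable), and
labels are re-ordered by ascending mean baseline RMSSD so they are
deterministic. No k-means consolidation pass is applied after cutting the
tree.

Clusters collapse to **responders** (mean stress RMSSD below mean baseline
*and* mean recovery above mean stress, each by more than a 5% relative
margin) versus non-responders. The margin implements the rule's intent — a
flat cluster is never "responsive" — robustly: without it, a flat cluster
whose condition means differ only by estimation noise is classified
responsive about a quarter of the time, and a flat cluster that absorbed a
few misassigned responders shows a spurious 2–4% mean dip. Genuinely
responsive clusters dip by ≥ 14% in every regime the package simulates; 5%
is the scale of epoch-RMSSD estimation error. Group differences in EI are
tested with two-tailed Mann–Whitney U tests in the convention of
`wilcox.test`: `W` is the U statistic of the first group, the p-value exact
for combined n ≤ 20 without ties and otherwise normal-approximate with tie
and continuity corrections.

At strong vagal withdrawal the collapse recovers the generator's responder
flags essentially perfectly; at the default moderate withdrawal an
occasional Ward cut leaves a mixed cluster and agreement drops to ~0.86 for
rare seeds — a genuine limitation of cluster-level (rather than
subject-level) classification.

## The synthetic-data generator

No public data accompany this analysis problem, so the generator defines the
study conditions; all of its anchors are resting-adult scales.

Each interval is `mean_ibi + resp_amp·sin(2πf_r t) + lf_amp·sin(2πf_lf t + φ)
+ ε`, with `ε ~ N(0, noise_sd²)`, φ seed-drawn, and the beat clock advancing
by each interval (`.rr_recurrence`, implemented in C++ for speed). Direct
additive modulation was chosen over an integral-pulse-frequency-modulation
model for analytic tractability: every metric has a closed form. Note one
consequence: linear interpolation of a sinusoid sampled at beat spacing Δ
attenuates its variance by (2/3)(1 + cos(2πfΔ)/2) — about 0.81 at 0.25 Hz
and 709 ms — so the A²/2 identity for interpolated-series variance holds
exactly only in the dense-sampling limit; tests assert the attenuated closed
form where it applies.

A subject is parameterized by a target RMSSD `T`, breathing frequency, and
mean heart rate (`rr_subject_config()`). Fixed spectral shares split `T²`
among the components: respiration 0.25, low-frequency 0.01, white noise
0.74. These shares, together with a 77.2% slow-breather fraction (breathing
at 0.08–0.11 Hz, below the 0.12-Hz validity floor; the rest at
0.15–0.35 Hz), reproduce the resting descriptive scales the package targets:
baseline RMSSD ≈ 33 ms, HR ≈ 85 bpm, HRV ≈ 7.0–7.3 ln ms², and ~77% invalid
RSA at baseline. The large noise share reflects that when most subjects
breathe below the respiratory band, most *successive-difference* variability
is not respiratory; the small LF share keeps the respiratory spectral peak
dominant for in-band breathers, which the validity rule requires.

**Population structure.** The latent log baseline RMSSD is a three-component
lognormal mixture of reactivity phenotypes — low/non-responsive
(≈ 19.8 ± 6.2 ms), mid (≈ 39.7 ± 11.8 ms) and high (≈ 73.4 ± 21.5 ms)
responsive groups, responders splitting ~4:1 between mid and high — because
resting vagal tone and stress reactivity are strongly coupled in adults. At
the default responder fraction of 0.48 the mixture marginal is
≈ 32.6 ± 19.6 ms. A Gaussian copula ties a latent EI trait
(`N(ei_mean = 100, ei_sd² = 15²)`) to the mixture quantile of log baseline
RMSSD at correlation `rho_ei_cvc` (default 0.2, i.e. partial η² ≈ 0.04, the
small-effect regime); the mixture quantile transform attenuates the
realized Pearson correlation by a factor 0.978, inside the recovery
tolerances. EI questionnaire scores (ability total + four branches, mixed
total + five composites) are generated around the latent traits with 0.75
loading for subscales and a 0.25 ability–mixed correlation; only the ability
trait is coupled to CVC. Demographic covariates (age, gender, caffeine, time
of day) are generated but deliberately not wired into physiology, so
covariate screening has a true null.

**Vagal withdrawal.** During stress, responders' vagally mediated components
— the respiratory amplitude *and* the beat noise, both parasympathetic in
this decomposition — are scaled by `1 − withdrawal` and restored in
recovery; the low-frequency component is untouched. The stress/baseline
RMSSD ratio is therefore `sqrt(q_lf + (1 − q_lf)(1 − w)²)`; the default
`stress_withdrawal = 0.30` yields a ≈ 30% drop for responders and ≈ 26–27 ms
population stress RMSSD. Scaling only the respiratory amplitude would cap
reactivity at ~13% once most subjects breathe below the band, far below
observed stress responses, which is why the noise component participates.

**Artifacts.** `inject_artifacts()` corrupts a series with missed, extra,
and ectopic beats (per-beat probabilities each capped at 0.2; ectopic
displacement uniform in 20–40% of the interval) while conserving elapsed
time exactly, and attaches a ledger indexed against the corrupted series so
detector sensitivity and false-positive rates can be scored exactly.

**Two lighter generators** support the statistical stages:
`simulate_reactivity_profiles()` draws per-condition RMSSD triples directly
from the same population model with an extra within-subject log-scale noise
(`sd_within = 0.15`, representing day-level physiological state the
stationary beat model does not contain — the full pipeline's own
within-subject variation is only windowing error, ~3%); and
`simulate_profile_mixture()` draws the three phenotype groups as
well-separated lognormal blobs (subject CV 0.08, within-condition CV 0.03,
groups ≥ ~8 within-group SDs apart) for cluster-recovery checks.

**What passing tests do and do not show.** The generator's beat series are
stationary within segments, with purely sinusoidal modulation, Gaussian
noise, instantaneous withdrawal at segment boundaries, and no heart-rate
response to stress. Real recordings drift, breathe irregularly, change rate
under load, and contain artifact bursts; passing the suite demonstrates that
the estimators and tests are correct and calibrated under the stated model,
not that the pipeline is robust to every field condition.

## Determinism and numerics

Every stochastic operation takes an explicit integer seed; identical seeds
give bit-identical output. Per-subject streams are derived from the master
seed with a counter-based multiplicative scheme (`derive_seed()`, exact in
double arithmetic below 2^53), so a subject's data do not depend on how many
subjects were generated before it. `run_pipeline()` threads its single run
seed through simulation and cross-validation fold assignment and rewrites
byte-identical CSVs on re-run. Degenerate inputs are handled explicitly:
constant windows yield `NA` log-variance sentinels rather than `-Inf`,
windows with fewer than 3 intervals are skipped and counted, rank-deficient
PCA warns and zero-variance components are dropped from standardized
clustering, and IBI files round-trip bit-exactly (`%.17g` on write, strtod
on read).

## Problem sizes used in the shipped checks

The end-to-end checks run at the sizes the analyses are designed for:
parameter recovery over 200 replicates of n = 100 per coupling value;
GLS size under the null over 500 replicates of n = 50 and power over 100
replicates of n = 100; artifact robustness over 100 corrupted recordings;
cluster recovery over 20 mixtures of n = 102 plus 5 full simulated studies;
and the default study at n = 102 subjects with the 300/90/300-s protocol.

## Known limitations

* The generator's additive-sinusoid RR model has no IPFM backend, no
  respiratory frequency drift, and no HR increase under stress; HR-reactivity
  analyses on simulated data are therefore null by construction.
* Cluster-level responder classification can misflag part of a mixed cluster
  at moderate withdrawal (see above).
* The correlation-matrix figure of the original analysis family sometimes
  includes variables (e.g. depression scores) that a given study did not
  collect; the variable list in `spearman_matrix()` is fully configurable
  and no fixed list is imposed.
* WFDB/EDF binary formats and QRS detection from raw ECG are out of scope;
  the pipeline starts from beat-detected IBI series.
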