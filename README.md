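# cvcreact

Cardiac vagal control (CVC) — the parasympathetic influence of the vagus
nerve over heart rate — is measured noninvasively from the variability of
interbeat (RR) intervals. `cvcreact` implements a complete, reproducible
pipeline for studying CVC across a **baseline → stressor → recovery**
protocol and relating resting and reactive vagal tone to trait scores such
as emotional intelligence (EI). It is aimed at psychophysiology researchers
who have per-subject IBI series (already beat-detected) plus a subject table,
and at methodologists who want a fully synthetic but statistically faithful
test bed for reactivity analyses.

## What it computes

From each subject's IBI series, over a 30-s moving window advancing 3 s at a
time within each protocol condition:

* **RMSSD** — root mean square of successive interval differences,
  `sqrt(mean((IBI[i+1] - IBI[i])^2))`, the primary time-domain vagal index;
* **HRV** — `ln` variance (ms²) of the IBI series linearly interpolated to a
  uniform 10 Hz grid (broadband, mixed autonomic influences);
* **RSA** — `ln` variance of the same series band-pass filtered to the
  respiratory band with a 241-tap linear-phase FIR whose half-amplitude
  frequencies are 0.12 and 0.40 Hz;
* **HR** — 60000 / mean(IBI);
* a **respiration validity check**: the dominant frequency of the IBI power
  spectrum must be at least 0.12 Hz, otherwise the RSA estimate is flagged
  invalid for that condition (slow breathers push respiratory power below
  the analysis band).

The per-window values are averaged into per-condition epoch means, and a
statistical battery mirrors a standard reactivity analysis: Spearman
correlation matrices with Bonferroni correction, log–log baseline
regressions with partial η² = SS_effect / (SS_effect + SS_error), stepwise
(AIC, bidirectional) EI-subscale selection, generalized-least-squares
repeated-measures models with unstructured within-subject correlation
(REML), AIC / likelihood-ratio model comparison, LASSO covariate screening
(10-fold CV, one-SE rule), and responder classification by PCA + Ward
hierarchical clustering with Mann–Whitney group tests.

A seeded synthetic-data module (`simulate_rr_series()`,
`simulate_session()`, `simulate_population()`, `inject_artifacts()`)
generates RR series with respiratory and low-frequency modulation, vagal
withdrawal during stress, beat artifacts, slow breathers, and a latent EI
trait coupled to log baseline RMSSD — so every downstream stage has a
testable ground truth.

## Worked example

```r
library(cvcreact)

cfg <- rr_subject_config(resp_freq = 0.25, target_rmssd = 33, mean_hr = 85,
                         duration = 690, seed = 42)
sess <- simulate_session(cfg, withdrawal = 0.4, responder = TRUE)
condition_summary(sess$ibi, sess$segments)
#> # A tibble: 3 × 9
#>   subject_id condition rmssd   hrv   rsa    hr resp_peak rsa_valid n_windows
#>   <chr>      <chr>     <dbl> <dbl> <dbl> <dbl>     <dbl> <lgl>         <int>
#> 1 s1         baseline   33.6  6.18  5.58  85.2     0.250 TRUE             91
#> 2 s1         stress     21.3  5.27  4.56  85.3     0.254 TRUE             21
#> 3 s1         recovery   33.4  6.22  5.71  85.0     0.250 TRUE             91
```

The stress epoch shows the expected vagal withdrawal (RMSSD 33.6 → 21.3 ms)
and full recovery; the respiration peak sits at the simulated 0.25 Hz, so
RSA is valid in every condition. (RSA/HRV are natural logs of ms²
variances; 91 and 21 are the numbers of 30-s windows in 300-s and 90-s
segments.)

A whole study, end to end:

```r
run <- run_pipeline(run_config(
  simulation = population_config(n_subjects = 102),
  seed = 1, output_dir = "cvc_run"
))
glance(run$results$clustering$clusters)
#> # A tibble: 1 × 5
#>       k pc1_variance pc2_cumulative responders non_responders
#>   <int>        <dbl>          <dbl>      <int>          <int>
#> 1     3        0.973          0.999         49             53
run$results$baseline_regression$ability
#> Model: rmssd_baseline ~ msceit_total (log-transformed variables)
#> n = 102, AIC = 156.19, logLik = -75.09
#>   msceit_total: F(1,100) = 5.57, p = 0.0202, partial eta^2 = 0.053
```

Two principal components carry >99% of the reactivity-profile variance;
Ward clustering of the standardized scores finds three groups that collapse
into 49 responders and 53 non-responders, and ability EI predicts baseline
RMSSD with a small effect (partial η² ≈ 0.05) — the magnitude regime the
generator is calibrated to. `run_pipeline()` also writes `metrics.csv`,
per-analysis JSON results, a cluster CSV, and a markdown report into
`output_dir`, and reruns byte-identically under the same seed.

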