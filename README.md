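# pupilci

Pupillometric listening-effort analysis for cochlear-implant (CI) cohorts:
a tested R pipeline linking speech-in-noise task difficulty (signal-to-noise
ratio, SNR) to peak pupil dilation (PPD), for hearing scientists and
audiologists who use pupillometry as an objective effort measure.

## The problem and the model

CI users report high listening effort in noise even when recognition
succeeds. The task-evoked pupil response indexes that effort: PPD — the
maximum of the baseline-normalized pupil trace,

```
rel(t) = (observation(t) − baseline) / baseline × 100,
```

computed from sentence onset to the response prompt — rises with task demand
up to a *tipping point* and falls as listeners disengage, tracing an
inverted U over difficulty. The package models each listener's effort curve
as a Gaussian bump

```
PPD(s) = A · exp(−(s − τ)² / (2w²))
```

over SNR `s`, with amplitude `A` (%), tipping point `τ` (dB) and width `w`
(dB), and asks how the curve's shape — each participant's mean PPD and the
quadratic coefficient of a parabola fitted over the 0–20 dB grid — relates
to individual factors: clinical word recognition, spectral-ripple
discrimination (SMRT), working memory (N-back d′), inhibition (Stroop),
nonverbal intelligence, subjective workload (NASA-TLX) and quality of life
(NCIQ).

Because the emulated study's raw recordings are not publicly deposited, a
synthetic-cohort generator with known ground truth (17 participants, 6 SNR
conditions 0–20 dB in 4 dB steps, 40 sentences each, 120 Hz traces with
blinks, hippus and tracking dropouts) stands in for them, so every stage —
trial cleaning, PPD extraction, mixed-effects psychometric models, the
individual-differences battery, the Bonferroni-corrected correlation grid —
is testable end to end. See `vignettes/listening-effort-pipeline.Rmd` for
the full methods account.

## Worked example

```r
library(pupilci)

profiles <- generate_profiles(17, seed = 1)        # cohort with latent effort curves
trials   <- simulate_ppd_trials(profiles, seed = 2) # 240 trial-level PPDs each
cells    <- aggregate(ppd ~ participant_id + snr, trials, mean)

round(tapply(cells$ppd, cells$snr, mean), 2)       # group mean PPD (%) by SNR
#>    0    4    8   12   16   20
#> 1.88 3.48 5.18 6.16 5.57 4.28

fit <- fit_polynomial_model(cells)                 # PPD ~ snr + snr² + (1 | participant)
fit$fixed_effects
#>          term  beta    se      z         p
#> 1 (Intercept)  5.66 0.248  22.84 1.79e-115
#> 2     snr_lin  1.38 0.146   9.45  3.32e-21
#> 3    snr_quad -2.64 0.249 -10.60  2.90e-26

shapes <- shape_table(cells)                       # per-participant mean PPD + curvature
cor(profiles$word_recognition, shapes$quad_coef, method = "spearman")
#> [1] -0.586
```

The group curve peaks mid-grid and the negative quadratic term (−2.64, z =
−10.6) confirms the inverted U; the negative Spearman correlation shows that
listeners with better word recognition have more sharply curved (earlier
tipping) effort functions — the individual-differences structure the
generator encodes and the analysis recovers.

Trace-level processing works the same way from raw samples:

```r
ev  <- simulate_behavior(build_schedule(profiles[1, ], seed = 3), profiles[1, ], seed = 4)
tr  <- simulate_trace(ev[1, ], profiles[1, ], seed = 5)   # 120 Hz, blinks + hippus
res <- preprocess_trial(tr, ev[1, ])                      # MAD → margins → cubic → smooth → PPD
res$metrics
#>   participant_id trial_id snr baseline_mm interp_fraction included ppd_pct
#> 1            P01 P01_T001   8        3.51               0     TRUE    10.5
```

The scripts under `analysis/` run the whole study-scale workflow in order
(`01_simulate.R` … `05_report.R`), writing all tables under `results/`.

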