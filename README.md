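# heatadapt

Predicting rectal-temperature adaptation after heat acclimatization and
heat acclimation from field-measurable surrogates.

## The problem

Whether a period of heat adaptation — outdoor summer training in natural
heat (heat acclimatization, HAz), a controlled exercise-heat chamber
protocol (heat acclimation, HA), or both in sequence (dual heat exposure,
DHE) — actually lowered an athlete's internal body temperature is the
criterion that matters for safety and performance, but measuring it
requires rectal thermistors or ingestible pills that are impractical in
field settings. Heart rate (HR), sweat rate (SR) and thermal sensation
(TS) are easy to collect with a chest strap, a scale and a perceptual
0–8 scale. `heatadapt` implements a pipeline that predicts the binary
rectal-temperature outcome (`ΔT_rec < 0` across an induction period) from
the pre/post deltas of those three surrogates:

1. **Deltas** — for each participant, three induction contrasts are
   formed from the baseline, post-HAz and post-HA heat-stress trials:
   ΔHAz = post-HAz − baseline, ΔHA = post-HA − post-HAz,
   ΔDHE = post-HA − baseline. All three are pooled into one analysis.
2. **Cut-points** — for each predictor delta, a depth-one decision-tree
   scan finds the threshold minimizing the label entropy
   `H(p) = −p log₂ p − (1−p) log₂(1−p)` of the split, and a selection
   policy balances the favorable side's improvement probability against
   its support. The published rules are ΔHR < −13 bpm, ΔSR > 0.3 L·h⁻¹,
   ΔTS ≤ −0.5.
3. **k-of-3 classifier** — an observation is predicted improved when at
   least `k` of the three rules are met (default `k = 2`).
4. **Diagnostics** — per-category positive predictive values,
   sensitivity/specificity, likelihood ratios
   (LR⁺ = sens/(1−spec), LR⁻ = (1−sens)/spec), a ROC sweep over
   `k ∈ {3,2,1,0}`, one-way ANOVA with Fisher's LSD contrasts of ΔT_rec
   across criteria-count categories, and Hedges' g effect sizes
   `g = J·(m_a−m_b)/s_p`, `J = 1 − 3/(4·df − 1)`.

Because per-participant trial data for this design are rarely shareable,
the package ships (a) a seeded synthetic cohort generator whose phase
summary statistics and predictor–outcome coupling emulate the published
regime, and (b) a deterministic 75-observation fixture that reproduces
the published contingency counts exactly.

## Worked example

```r
library(heatadapt)
res <- run_pipeline(pipeline_config(fixture = TRUE))
print(res$report)
```

```
Rectal-temperature adaptation diagnostics (k = 2 )

Improvement probability by number of criteria met:
    0 criteria: 6 / 16 improved (37.5%)
    1 criteria: 22 / 36 improved (61.1%)
  2-3 criteria: 22 / 23 improved (95.7%)

At >= 2 criteria: sensitivity 0.44, specificity 0.96, LR+ 11.0, LR- 0.58
...
ANOVA of d_trec across categories: F(2, 72) = 24.26, p = 8.835e-09
Pairwise (LSD) contrasts of d_trec:
  2-3 vs 1   -0.58 degC [-0.78, -0.38], g = -1.58 (large), p = 1.126e-07
  2-3 vs 0   -0.74 degC [-0.98, -0.50], g = -1.82 (large), p = 3.682e-08
  1 vs 0     -0.16 degC [-0.38, +0.06], g = -0.45 (small), p = 0.1531
```

Reading: when two or three of the surrogate criteria are met, 95.7% of
observations truly show a lower rectal temperature (22 of 23), with
specificity 0.96 — a strong rule-in signal (LR⁺ = 11) but limited
sensitivity (0.44): many true improvers move fewer than two surrogates.
The mean ΔT_rec improvement is 0.58 °C greater than in the one-criterion
group and 0.74 °C greater than with no criteria met.

A simulated cohort goes through the same stages:

```r
res <- run_pipeline(pipeline_config(
  generator = generator_config(n_participants = 25, seed = 42),
  search_cutpoints = TRUE, grid_step = NULL))
res$rules$d_hr      # data-driven heart-rate cut-point
res$candidates$d_hr # full threshold/probability/support audit table
```

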