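---
title: "Methods: cut-point prediction of rectal-temperature adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cut-point prediction of rectal-temperature adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatadapt)
```

## The measurement setting

Endurance athletes complete three standardized 60-minute heat-stress
trials: at baseline, after a summer of outdoor training in natural heat
(heat acclimatization, HAz), and after a subsequent short chamber
protocol (heat acclimation, HA; the two in sequence are the dual heat
exposure, DHE). Each trial yields four endpoints: peak heart rate (bpm),
peak thermal sensation on a 0–8 Likert scale, whole-trial sweat rate
(L·h⁻¹), and end-of-trial rectal temperature (°C). The criterion of
adaptation is a *drop* in end-of-trial rectal temperature across an
induction period; the question the pipeline answers is how well the
field-measurable deltas of the other three endpoints predict that drop.

Per participant, three induction contrasts are formed (post-HAz −
baseline, post-HA − post-HAz, post-HA − baseline) and pooled into a
single analysis. Pooling treats the three contrasts from one participant
as independent observations; that is how the source analysis was run,
and the pipeline reproduces it as-is rather than fitting a
repeated-measures alternative. The improvement label is strict
negativity, `d_trec < -tolerance` with `tolerance = 0` by default and a
tie counted as not improved; the margin is exposed as a parameter
because reasonable users may want a minimum physiologically meaningful
drop (e.g. 0.05 °C, half the instrument resolution) rather than any
negative rounding.

## Cut-point discovery

For one predictor delta, the scan is a depth-one decision tree: each
candidate threshold splits the pooled observations into two sides, and
the quality of the split is the information gain

\[ IG(t) = H(p) - \tfrac{n_L}{n} H(p_L) - \tfrac{n_R}{n} H(p_R), \qquad
   H(p) = -p \log_2 p - (1-p)\log_2(1-p), \]

with the convention \(0 \log_2 0 = 0\). Entropy is measured in bits;
the base only rescales and never changes which threshold wins. Only
depth-one splits are implemented, because the published probabilities
are all "after one split" figures and no deeper tree is ever grown.

Candidate thresholds are midpoints between consecutive distinct sorted
values (every achievable binary partition, with the threshold placed
midway for stability) or, when `grid_step` is set, multiples of the step
spanning the observed range — the natural choice when thresholds should
sit on the instrument grid (1 bpm, 0.01 L·h⁻¹, 0.5 scale units).

The favorable side of each variable is fixed a priori by the sign
convention of adaptation — heart rate and thermal sensation fall,
sweat rate rises — and is not searched. Boundary strictness follows the
published rules (strict for HR and SR, non-strict for TS); it is
configurable per rule because the source is not perfectly consistent
about the TS boundary (≤ −0.5 in some statements, < −0.5 in others);
the default follows the more frequent ≤ form.

**Selection policy.** The published procedure selects a balance of "the
highest probability and the highest number of cases", illustrated by
preferring an 82%-with-22-cases split over a 78%-with-41-cases one.
`heatadapt` makes that balance explicit as a two-policy system:

* `max_ppv_min_support` (default): discard candidates whose favorable
  side holds fewer than `ceiling(min_support_fraction × n)` observations
  (default fraction 0.25, approximating the accepted 22-of-75 support),
  then maximize the favorable-side improvement probability;
* `max_info_gain`: the pure entropy-minimizing split.

Ties break toward larger favorable support, then toward the threshold
nearest zero (the most conservative claim about how much change is
required). The full candidate table is always returned so the trade-off
can be audited, and `select_cutpoint()` errors rather than silently
relaxing when no candidate meets the support floor.

## The classifier and its evaluation

`count_criteria()` applies the three rules and predicts improvement when
at least `k` are met; `k` defaults to 2 but is exposed so the ROC over
`k ∈ {3,2,1,0}` can be traced. The evaluation layer is deliberately
classical: per-category PPVs (with counts 2 and 3 collapsed into one
"2–3" category, as in the source contingency summary), the 2×2 table at
`k`, sensitivity/specificity, likelihood ratios (LR⁺ reported as an
explicit `Inf` marker at specificity 1 so ROC sweeps never abort),
one-way ANOVA of `d_trec` across categories with Fisher's LSD pairwise
contrasts (unadjusted t contrasts on the pooled error term — that is
what LSD means), and Hedges' g with the small-sample correction
`J = 1 − 3/(4·df − 1)`, `df = n_a + n_b − 2`. The magnitude bands
(small 0.2–0.49, medium 0.5–0.79, large > 0.8) leave gaps at 0.49→0.5
and 0.79→0.8 as usually printed; they are closed as half-open intervals
[0.2, 0.5), [0.5, 0.8), [0.8, ∞), with |g| < 0.2 labelled "negligible".
The univariate logistic fits report both Cox–Snell and Nagelkerke
pseudo-R² side by side, since published "r²" values for such fits rarely
say which variant they are; complete separation is flagged via
`converged = FALSE` rather than reported as a finite slope.

ANOVA and the logistic fits are delegated to `stats::aov()` and
`stats::glm()` (IRLS with gradient tolerance 1e-8, at most 100
iterations); the test suite cross-checks them against an independent
sum-of-squares recomputation and the closed-form saturated 2×2 logistic
solution, and checks Fisher's LSD against the pooled-variance t-test in
the two-group limit.

## The synthetic cohort generator

Raw per-participant trials for this design are typically unavailable, so
the generator provides a cohort whose *phase-level* behaviour matches the
published summary statistics: HR 143 ± 12 → 138 ± 14 → 134 ± 11 bpm,
rectal temperature 38.29 ± 0.37 → 38.25 ± 0.42 → 38.03 ± 0.39 °C, TS
5.6 ± 0.6 → 5.5 ± 0.5 → 5.1 ± 0.6, and SR rising to 1.76 ± 0.43 then
1.93 ± 0.46 L·h⁻¹. The baseline sweat-rate mean is not part of that
table; the default 1.70 ± 0.40 L·h⁻¹ is chosen so a small positive
acclimatization delta lands on the printed post-HAz mean. Stage-delta
means are differences of the printed phase means (HR −5, −4; T_rec
−0.04, −0.22; TS −0.1, −0.4; SR +0.06, +0.17), i.e. derived from rounded
values.

The model for participant *i* and variable *v* is

\[ \Delta_{v,i} = \mu_v - s_v \beta_v u_i + \varepsilon_{v,i}, \qquad
   u_i \sim N(0,1), \ \varepsilon_{v,i} \sim N(0, \tau_v), \]

where `u_i` is a single latent responsiveness factor shared by all four
variables and both stages, and `s_v` is +1 for HR/T_rec/TS and −1 for
SR. This is an assumption, not an estimate: the source reports no
between-variable correlations, and one shared factor is the simplest
structure that produces the predictive coupling the classifier needs.
Defaults β = (8 bpm, 0.30 °C, 0.4 units, 0.20 L·h⁻¹) and τ = (5 bpm,
0.15 °C, 0.3 units, 0.10 L·h⁻¹) place the two-or-three-criteria PPV of
the published rules in the published high-accuracy regime; the test
suite validates exactly that calibration property across 50 seeds and
nothing finer. Phase values are accumulated (baseline + stage deltas),
clipped to physiologic bounds (HR 90–210 bpm, T_rec 36.5–41.0 °C, TS
0–8, SR 0.1–4.0 L·h⁻¹), and quantized to the instrument resolution.
A single global seed drives one RNG stream, so the determinism contract
is whole-cohort: identical configuration ⇒ byte-identical output files.

What the generator does *not* emulate: within-trial time courses,
environmental covariates, training-load heterogeneity, non-normal tails,
or any dependence structure beyond the one latent factor. Tests passing
on synthetic cohorts therefore demonstrate the pipeline's correctness
and its behaviour in the published summary-statistics regime — not
validity of the published cut-points for new populations.

## Numerical choices

* **Quantization and exact arithmetic.** Stored phase values are snapped
  to the measurement grid and canonicalized to the double nearest their
  printed decimal form, which makes the trial-table round trip through
  delimited text an exact identity. Deltas are differenced via integer
  grid indices, so the combined DHE delta equals the sum of the two
  stage deltas exactly on the grid (and to 1e-12 on the represented
  doubles — decimal steps such as 0.01 are not exactly representable in
  binary).
* **TS resolution.** The thermal-sensation scale is anchored at
  half-point steps, so values are quantized to 0.5 units. A side effect
  is that the configured TS stage means (−0.1, −0.4) are not
  representable per participant in a noise-free cohort: the quantized
  phase means 5.5/5.5/5.0 yield deltas 0 and −0.5. With realistic noise
  the ensemble means still match the configured values.
* **Degenerate inputs.** Empty split sides are void candidates (gain 0,
  favorable probability `NA`); an all-constant ANOVA errors rather than
  returning 0/0; empty truth classes in the 2×2 table are named errors;
  empty PPV categories are omitted with a warning.

## Parameter recovery as a design check

The recovery experiment in the acceptance suite plants a known boundary:
with all stage-delta means set to zero and strong coupling (β_HR = 8,
τ_HR = 2), improvement and the heart-rate delta share the latent
boundary u = 0 in *every* contrast, so the planted cut sits at 0 bpm for
the pooled sample. (With non-zero means the boundary differs between
single-stage and combined contrasts, and no single planted value
exists.) Recovery uses the `max_info_gain` policy: the support-floor PPV
policy by construction walks to the most extreme threshold that still
meets the floor rather than to the planted split, so entropy
minimization is the right instrument for this check. The suite requires
the recovered threshold within one 1-bpm grid step of the boundary in at
least 80 of 100 seeds at 200 participants; at the chosen noise level the
observed rate is ~0.85.

Problem sizes used by the tests and the acceptance script — 75
observations for the fixture path, 2000 participants for the
generator-mean check, 100 seeds × 200 participants for recovery, 50
seeds × 200 for calibration — were chosen to make Monte-Carlo error
comfortably smaller than the tolerances being asserted.

## Known limitations

* The pooled analysis ignores within-participant dependence between the
  three contrasts; inferential p-values inherit that optimism from the
  source design.
* The published effect sizes for the group contrasts are not exactly
  recoverable from rounded printed summaries, and the fixture pins group
  *means*, not spreads; fixture-derived Hedges' g values are therefore
  indicative, not reproductions.
* The published specificity for the "more than one variable" rule is
  internally consistent with its likelihood ratios but not with the
  printed per-category counts; `heatadapt` always reports count-derived
  values and leaves the discrepancy to the reader.
* Cut-points discovered on small cohorts (n = 25 × 3 contrasts) are
  noisy; the candidate table, not the single selected threshold, is the
  honest output at that scale.
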