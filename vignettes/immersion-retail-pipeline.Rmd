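---
title: "From sales-associate Immersion to purchase prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sales-associate Immersion to purchase prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immersr)
```

immersr analyses retail service encounters in which a sales associate wears a
physiological sensor producing a 1 Hz "Immersion" index — a commercial
composite of attention and emotional resonance derived from cardiac (PPG)
rhythms, on an arbitrary positive scale with session means around 4.4 units.
The package asks one scientific question end to end: does the associate's
neurophysiology during an encounter carry enough signal about the *customer's*
experience (physiological contagion) to predict whether, and how much, that
customer buys?

This vignette records the models, the parameter choices, and the reasoning
behind the design decisions. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## Session-level Immersion statistics

A session trace is the Immersion series $n(t)$ sampled at 1 Hz from the
greeting ($t = 0$) to the customer's departure ($t = T$). Four statistics
summarize it:

* total Immersion $I = \sum_t n(t)$ (Immersion·seconds at 1 Hz);
* average Immersion $I / T$;
* the session threshold $M = \mathrm{median}(n) + 0.5\,\mathrm{SD}(n)$, with
  the sample SD ($n-1$ denominator) and midpoint median;
* **Peak Immersion** $= \frac{1}{I}\sum_{t:\, n(t) > M} n(t)$, the fraction of
  total Immersion carried by the above-threshold samples.

Peak Immersion is dimensionless and lies in $[0, 1)$; normalizing by $I$
removes dwell-time differences, and because median, SD and sums all scale
linearly, the statistic is invariant to rescaling of the platform's arbitrary
units. The brain returns to basal activity during long recordings, which is
why this peak-weighted fraction tends to predict behavior better than the
session mean.

Numerical choices:

* The integral is a discrete 1 Hz sum — the platform emits one sample per
  second, so no interpolation is warranted.
* The notation "sum of $n(t) > M$" admits three readings: count the
  above-threshold seconds, sum their full values, or sum only the exceedance.
  Summing full values is the default because only that variant produces
  magnitudes near the observed 0.24–0.26 when session means are ~4.4; the
  `indicator` and `excess` variants remain available for sensitivity
  analysis.
* Ties at exactly $M$ are excluded (strict inequality): a constant trace has
  Peak Immersion exactly 0.
* The threshold is computed per session — the statistic describes *this*
  encounter, not the associate's week.
* Sampling gaps of at most 5 s are forward-filled; longer dropouts invalidate
  the session. Sessions shorter than 10 samples are rejected because the SD
  is unstable (callers may lower `min_samples` for didactic examples).

## The procedural-utility choice model

A shopper allocates income $M$ between two stores at a common price $p$;
store 1 adds experiential value through the multiplier $e$ on its log
utility:

$$\max_{c_1, c_2}\; e \ln c_1 + \ln c_2
  \quad \text{s.t.}\quad p c_1 + p c_2 \le M .$$

The Cobb–Douglas solution spends $M e/(1+e)$ in the experience store,
independent of $p$. A second variant, $M e/(p+e)$, is exposed as
`"as_printed"`: it is a form that circulates with the 1 replaced by the
price, coincides with the share form at $p = 1$, and is dimensionally
inconsistent elsewhere — the package keeps both, defaults to the derived
share, and lets a grid-search maximizer (`numeric_optimum()`) arbitrate:
the grid search selects the derived share everywhere it has been tested.
The cohort simulator sets $p = 1$ (numeraire) where the two coincide.

The model's three predictions — more spending in the experience store
whenever $e > 1$, dwell time increasing in $e$ (via the proportionality
$e \propto t$, `predicted_dwell()` with slope $\kappa$ minutes per unit of
$e$), and spending increasing in $e$ — are property-tested on a grid of $e$
values. $e$ is accepted on $[0, \infty)$ (with a flagged corner solution at
$e = 0$) even though the economic story needs $e > 1$. Credit is excluded:
total spending cannot exceed income.

## The cohort simulator

`generate_cohort()` is the ground truth of the package: a two-store shopper
cohort in which every downstream claim is checkable because the latent
experiential value $e_i$ is retained. Per session:

* $e_i \sim \mathrm{LogNormal}(\mu_e, \sigma_e)$;
* dwell $= \kappa\, e_i\, \varepsilon$, $\varepsilon$ lognormal — the
  proportionality of the choice model plus multiplicative noise, giving the
  heavy right tail seen in luxury-retail dwell times;
* purchase incidence $\sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\beta_0 +
  \beta_1 e_i))$ — the zero-inflation gate;
* purchase amount (given incidence) $= M\, e_i/(1+e_i)\,\varepsilon'$ — the
  Cobb–Douglas share at $p = 1$ with lognormal noise;
* the associate's trace: a per-session baseline offset plus a stationary
  AR(1) fluctuation, overlaid with burst episodes (Poisson counts, geometric
  durations, gamma amplitudes) whose rate increases gently with
  $e_i/(1+e_i)$.

Making *Peak* Immersion (bursts) rather than average Immersion the monotone
correlate of $e$ is deliberate: the peak statistic, not the mean, is the
better behavioral predictor in this setting, and the simulator encodes that
asymmetry.

The default profiles are calibrated once against the observed store
summaries of the field study the package emulates — WS (women's store,
n = 31): dwell ≈ 32 min with SD comparable to the mean, purchase frequency
≈ 0.73, mean amount ≈ \$266, average Immersion ≈ 4.42, Peak Immersion
≈ 0.242; MS (men's store, n = 25): dwell ≈ 15 min, frequency ≈ 0.52, amount
≈ \$140, average Immersion ≈ 4.49, Peak Immersion ≈ 0.255, and a
dwell–amount correlation near 0.4. The calibration fixes the lognormal
parameters of $e$, the dwell and amount noise scales, the logistic link
($\beta_0 = -1.05$, $\beta_1 = 1$ for WS; $\beta_0 = -2.45$, $\beta_1 = 2$
for MS — the men's store links purchases more tightly to the experience,
which is what its stronger dwell–purchase correlation demands), and the
burst process (about 6.5–6.9 two-second episodes per minute of unit
amplitude over a baseline near 4.2). These defaults *are* the study
conditions; tests and the acceptance script do not move them.

What the simulator does not emulate: customer-side physiology (never
measured), the proprietary conversion from cardiac data to Immersion (only
the 1 Hz summary statistics are mimicked), diurnal or weekday structure, and
associate fatigue across sessions. Passing tests therefore demonstrate that
the *analysis chain* recovers known structure — not that real stores behave
like the generator.

One observed quantity is reproduced only qualitatively: the session-to-session
SD of Peak Immersion (simulated ≈ 0.03 vs 0.017 observed in the WS arm).
Tightening it further would require implausibly dense burst processes; the
cohort means, which the analyses consume, match within the stated bands.

## Parametric tabular synthesis

`fit_synthesizer()` implements sequential parametric synthesis: variables are
visited in a causal order (demographics → Immersion metrics → dwell →
purchase incidence → amount), the first modeled marginally, each later one by
a conditional model given all earlier ones — normal-linear for continuous
variables, logistic for binary flags, empirical proportions for the
low-cardinality store label. Heavy-tailed dwell and amount are
log1p-transformed before fitting; the amount is *gated* by the incidence
flag (fitted on purchasers, sampled as zero otherwise), reproducing
zero-inflation. Synthesis is per store, matching the store-stratified
analyses. A constant binary flag (possible at n ≈ 30, e.g. an all-female
arm) is kept as a degenerate Bernoulli; a constant continuous variable is an
error, since no conditional model is identifiable.

Fidelity is reported per variable: a two-sample Kolmogorov–Smirnov test and
a quantile-grid MSE — the mean squared difference of the 1st–99th
percentiles of observed vs synthetic, a sample-size-independent distance
that is exactly 0 for identical tables. The overall figure averages
variance-standardized quantile MSEs so variables on different scales
contribute comparably. "MSE between synthetic and observed data" has no
canonical definition; the quantile grid was chosen because it is invariant
to the synthetic sample being much larger than the observed one.

The expansion default is 10,000 synthetic rows per store. Note what
expansion can and cannot do: it sharpens estimates *of the small sample's
joint distribution*, so a path estimate that is noise at n = 31 becomes a
confidently estimated noise artifact at n = 10,000. The acceptance suite
treats the expanded mediation paths accordingly (reported, not asserted),
while asserting the pathway on large directly simulated cohorts.

## Statistical battery

Between-store comparisons use the classical pooled-variance Student's t
(df $= n_a + n_b - 2$), not Welch: reconstructing published comparisons from
printed (M, SD, N) triplets with the pooled formula reproduces the printed t
values within rounding, which Welch does not. The battery accepts either raw
samples or summary triplets — the consistency of the two input modes is
itself tested. Proportions are compared by 2×2 chi-squared (optional Yates
correction), associations by Pearson r with t-based p-values (one-tailed
p-values halve the two-tailed p in the observed direction), and
distributional equivalence by the two-sample KS test. No multiple-testing
correction is applied, matching the analysis style the battery reproduces.

## Mediation

The causal chain Peak Immersion → dwell → purchases is estimated by two
least-squares equations (the Gaussian maximum-likelihood estimator):

$$\text{dwell} = i_1 + a\,\text{peak} + \gamma' Z, \qquad
  \text{purchase} = i_2 + c'\,\text{peak} + b\,\text{dwell} + \delta' Z,$$

with indirect effect $ab$, direct effect $c'$, and the exact linear identity
$\text{total} = c' + ab$. Inference on $ab$ uses a percentile bootstrap over
row resampling (default 5,000 replicates; at least 1,000 for reported
intervals) with the closed-form Sobel z as a complement. Covariates (`loyal`,
`companion`) enter both equations when enabled. The outcome is the
continuous purchase amount; fitting is store-stratified in the pipeline. The
pipeline logs a low-power warning when a stratum has fewer than 100 rows;
the minimum is 20 rows so that the 25-session store arm remains analyzable.

## Purchase prediction

After discretizing purchases (`purchased = amount > 0`), three heterogeneous
tree learners are tuned and combined: a random forest, gradient boosting
(xgboost), and extremely randomized trees (ranger with the extratrees split
rule) as the third learner — a distinct tree-randomization algorithm filling
the "third tree learner" slot of the ensemble contract. The ensemble
prediction is the unweighted mean of the three predicted probabilities; no
weighting scheme is assumed. Features default to Peak Immersion, dwell time,
and the loyal/companion controls.

Hyperparameters are selected per learner by exhaustive grid search under
inner 3-fold cross-validated accuracy; performance is then reported from
outer stratified 5-fold cross-validation (a stratified 50/50 holdout mode is
available to mirror half-for-training designs). Pooled metrics aggregate
out-of-fold confusion counts and predictions — never fold means. The default
grid deliberately favors strong smoothing (forest node sizes 25–75, boosting
depth 1–2 at learning rate 0.05, extra-trees node sizes 40–100): with a
handful of behavioral features and a noisy label, deep trees overfit and can
drag the ensemble below the always-included logistic-regression baseline.
AUC is computed as the rank (Mann–Whitney) statistic with ties counted half;
MSE is the Brier score of the predicted probabilities. Classifying the
discretized label directly is the default; a regress-then-threshold variant
was considered and rejected as the primary path because the label, not the
amount, is the quantity the classifier is scored on.

## Pipeline, seeds, and problem sizes

`run_pipeline()` chains simulate → metrics → synthesize → stats → mediate →
predict, each stage reading the previous stage's CSV/JSON artifacts and
logging row counts and key statistics. A single global seed is expanded into
per-stage child seeds by the documented scheme in `stage_seed()`
(`(seed · 131 + 1000 · stage_index) mod (2^31 - 1)`), so any stage can be
rerun in isolation with its original stream. Two runs with the same config
and seed produce byte-identical artifacts; the manifest records the config
hash, seed, timings and file inventory. The default pipeline seed is 1969,
the conventional synthesis seed for this analysis family.

The test and acceptance workloads use deliberately moderate problem sizes —
cohorts of a few hundred to two thousand sessions, 100-replicate coverage
and fidelity studies, bootstrap sizes of 300–500 — chosen so the full chain
exercises every claim at desk scale; all scale linearly if larger runs are
wanted.

## Known limitations

* The Immersion index itself is proprietary; the simulator matches its
  published summary statistics, not its internals, and no PPG-to-Immersion
  conversion is attempted.
* The synthesizer is parametric by design (normal-linear/logistic chains);
  strongly non-Gaussian conditionals beyond the modeled log transforms are
  out of reach, and no disclosure-risk assessment is made.
* Mediation estimates carry the usual caveat: the model's causal reading
  rests on its own assumptions; no sensitivity analysis for unmeasured
  confounding is provided.
* Estimating the experiential value $e$ from real purchase data is not
  attempted — the model is used generatively, not econometrically.
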