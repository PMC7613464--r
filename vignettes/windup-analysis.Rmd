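---
title: "Quantifying wind-up: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wind-up: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windupr)
```

Temporal summation of pain — "wind-up" — appears at three measurement
levels: intracellular calcium handling in spinal neurons, the firing
of wide-dynamic-range dorsal horn neurons under repetitive C-fibre
strength stimulation, and the psychophysical wind-up ratio in humans.
This vignette documents the models behind each analysis stage, every
tunable convention, what the synthetic generators emulate, and the
choices made where a published protocol leaves the details open.

## Repeat-reliability quality control of calcium traces

Cultured dorsal horn preparations contain glia and heterogeneous
neurons; trace-level quality control must find the cells that respond
reliably to all three depolarising pulses. With the three epochs
aligned at their pulse onsets (`segment_epochs()`), the score is a
signal-power decomposition:

* **explainable variance** — the population variance over time of the
  pointwise mean across the three repeats: the variance a
  repeat-consistent response explains;
* **total variance** — the population variance of all samples of all
  repeats pooled about the grand mean;
* **SNR** = explainable / (total − explainable).

A threshold of 1 marks signal power equal to noise power; cells pass
only strictly above it. Population variances (divide by *N*) are used
in both terms so the identities are exact: the score is invariant
under adding a constant to the trace or rescaling it, explainable
variance never exceeds total, and three identical non-constant repeats
score `Inf` while a constant trace scores 0. Whether the original
Matlab implementation pooled variances or averaged per-epoch variances
is not knowable from the protocol; pooling was chosen as the standard
repeat-reliability decomposition and is recorded in the pipeline
manifest. Under pure noise the expected score is near 0.5 (the mean of
three repeats retains a third of the noise variance), which is why a
threshold of 1 rejects essentially all non-responders at 90-sample
epochs.

## Per-pulse calcium metrics

* **Baselines** are means over a 15 s window before each pulse onset
  and over the final 15 s. The window length is a package choice (the
  protocol names the baselines but not the window): long enough to
  average 1 Hz noise, short enough to avoid decay tails; it is
  configurable and recorded in output.
* **Peaks** are read at the fixed times pulse onset + duration (90,
  180, 270 s under the default schedule), because the protocol states
  explicit read-out times; a window-maximum mode is retained for
  robustness studies.
* **AUC** is the discrete trapezoid of (value − reference) over each
  epoch, negative contributions retained. The reference is a scalar
  per cohort — by default the cohort mean of start baselines — so AUC
  comparisons between cohorts are not driven by baseline offsets.
  Whether the original integration spanned pulse-only or
  pulse-plus-washout is unstated; the full epoch is used and recorded.
* **Tau** comes from fitting $f(t) = A e^{-t/\tau}$ to each decay
  segment (nominal peak to next onset), after shifting the segment so
  its final value is zero. Because the final *sample* only
  approximates the true asymptote, the model carries a free offset
  term initialised at zero; without it a noiseless exponential is
  recovered with a ~2% bias, with it recovery is exact to machine
  precision. Starting values are $A_0$ = first segment value and
  $\tau_0$ = interpolated time to reach $e^{-1} A_0$ (37% of the
  initial amplitude — the defining property of the time constant).
  Degenerate segments (non-positive initial amplitude, e.g.
  monotonically rising) return a fit-failure record rather than an
  error. Implausible fits are removed by the cohort rule: τ > 200 s
  (dorsal horn) or τ > 100 s (DRG).

## In vivo ΔF/F and response detection

After pointwise background-ROI subtraction,
$\Delta F/F = 100\,(F_t - F_0)/F_0$ with $F_0$ the mean over the full
2-minute pre-stimulus baseline (configurable). ROIs with non-positive
$F_0$ cannot be normalised and are excluded with a flag.

A response to an event is called against the threshold
$1.2\,\mu(B_E) + 2\,\sigma(B_E)$, where $B_E$ is the 5 s baseline
starting 10 s before the event. `call_response()` applies this rule in
whatever units its trace carries. The recording-level wrapper applies
it on the fluorescence-relative-to-baseline scale ($F_t/F_0$ in
percent, i.e. ΔF/F + 100), where the pre-event baseline sits near
100%: there the factor 1.2 means "20% above the baseline fluorescence
intensity", matching the protocol's description, and a stationary
pure-noise ROI essentially never crosses. Applied instead to a
zero-mean ΔF/F trace the same rule would degenerate to a ≈2σ test
with double-digit false-positive rates over multi-sample windows —
the motivation for this convention. The post-event search window is
not specified by the protocol; it defaults to the inter-stimulus
interval for per-pulse calls and to train duration + 5 s for
whole-train calls, and is recorded in the output.

Aggregation is two-level — ROI maximum → animal mean → cohort
mean ± SEM — because the animal, not the ROI, is the experimental
unit. A single-animal cohort reports its SEM as missing.

## Spike-train wind-up statistics

Latencies after each stimulus are banded half-open and
lower-inclusive: A-fibre [0, 50) ms, C-fibre [50, 250) ms,
post-discharge [250, `pd_end`) ms. A convention is required at the
printed boundaries; lower-inclusive was chosen, so a 50 ms spike is
C-fibre. The post-discharge upper bound is not printed; it defaults to
the inter-stimulus interval and is configurable. Latencies at or
beyond `pd_end` are reported as overflow, never silently dropped, so
band totals + overflow always equal the spike count.

With per-stimulus counts $y_i$ over a 16-stimulus train:
Input $= 16\,y_1$ (the non-potentiated response) and
wind-up $= \sum y_i -$ Input, which may be negative under
habituation. The growth of $y_i$ is modelled as one-phase
association, $y(i) = y_0 + (P - y_0)(1 - e^{-k(i-1)})$, the standard
curve for wind-up acceleration; the index is shifted so $y(1) = y_0$
exactly. The published analysis names non-linear regression but not
the curve; one-phase association is assumed and recorded. Flat
responses leave $k$ unidentifiable and return $k = 0$ with a flag.
Receptive-field positivity requires strictly more than 30 spikes per
5 s (proportional for other windows), and EMG afferent volleys are
classed by conduction velocity: Aβ [20, 100), Aδ [2, 20),
C [0.05, 2) m/s.

## Human wind-up ratio and supporting statistics

WUR = mean of the five train ratings / mean of the five single
ratings. The protocol wording admits either the ratio of means or the
mean of per-repeat ratios; ratio of means is the default (it is
defined whenever any single rating is positive) with the per-repeat
variant available. Records with WUR > 6 — almost always caused by
near-zero single ratings — are excluded, strictly greater-than, and
kept/excluded always partition the input. Summaries are medians and
type-7 (linear interpolation) IQRs.

The 50% withdrawal threshold follows the Dixon up-down convention
$T_{50} = 10^{X_f + k\delta}$. The pattern constant $k$ is not read
from the historical printed table but computed from the model that
generated it: a normal psychometric function on log₁₀ force with
spread equal to the ladder spacing, maximised over the threshold
location given the observed sequence. This keeps the estimator
self-contained and handles any ladder; sequences that run off either
end return the ladder extreme. In simulation against a deterministic
threshold placed between two filaments, the median estimate over all
starting positions lies within one ladder step of the truth.

Box-Cox tuning transforms the data at each λ on a −3…3 grid (step
0.1, unscaled form $(x^\lambda - 1)/\lambda$, natural log at 0) and
picks the λ whose Lilliefors statistic — the KS distance to a normal
with estimated mean and SD — is smallest, ties broken toward λ = 1.
The statistic uses the conventional $n-1$ sample SD, matching the
reference implementation in `nortest`, so duplicating a dataset
changes D only at order $1/n$. The procedure is scale-invariant per
λ, hence the tuned λ is unaffected by rescaling the input. A caveat
on identifiability: when data sit many SDs from zero the Box-Cox
family is locally affine and λ is weakly identified; recovery of
λ ≈ 1 on normal data should only be expected when the coefficient of
variation is appreciable (the tests use mean 5, SD 1). Monte-Carlo
p-values, when requested, re-estimate the parameters on each simulated
standard-normal null sample.

## Association power

For a single SNP explaining a fraction $R^2$ of trait variance in a
linear model, the test statistic is asymptotically 1-df chi-square
with noncentrality $n R^2 / (1 - R^2)$; power is the upper tail at
the central $(1-\alpha)$ quantile, with $\alpha = 5.3\times10^{-8}$
the genome-wide threshold. Covariate degrees of freedom are ignored —
a documented approximation, negligible at $n \approx 1000$. The
simulation cross-check draws Hardy–Weinberg genotypes, scales the
additive effect to the target $R^2$ against unit residual variance,
and tests the OLS slope with the large-sample Wald (normal) critical
value; the normal rather than finite-df t quantile is used
deliberately so that the two routes estimate the same approximation
(at genome-wide α the t quantile is enough larger to bias the
comparison by 1–2% at n = 1000).

```{r power}
round(100 * analytic_power(1000, 0.03, 5.3e-8), 1)
round(100 * analytic_power(1000, 0.05, 5.3e-8), 1)
```

## The synthetic generators

Each generator draws from a single seeded stream per call (the
caller's RNG state is untouched) and returns a ground-truth table with
one row per cell, neuron or participant; equal seeds give
bit-identical output.

* `sim_ratio_traces()` emulates the statistical structure the in
  vitro analysis assumes: a linear ramp to peak across the 30 s pulse
  window (the rise shape within the pulse is unspecified by the
  protocol; a linear ramp is the simplest monotone choice and is
  configurable), exponential decay with per-cell τ, additive Gaussian
  noise, plus non-responder and dying-cell classes. The dying class —
  a first-pulse response followed by a sustained elevated level with
  no later peaks — is a modelling choice, since the protocol describes
  it only qualitatively. The default responder fraction (0.73) mirrors
  the retention rate reliability filtering shows in dorsal horn
  cultures.
* `sim_dff_recording()` superimposes stimulus-locked transients
  (instant rise, exponential decay, linear summation) on a noisy
  baseline at 4 Hz with a 2-minute pre-stimulus period; at 1 Hz trains
  with decay slower than the interval the transients summate, as in
  the tissue.
* `sim_spike_table()` draws per-stimulus counts around the one-phase
  association law — Poisson by default, deterministic rounding or
  negative binomial (variance = c·mean) as options — and assigns each
  spike a latency uniform within its multinomially drawn band.
  Defaults (y₀ = 27, plateau = 70, k = 0.177, 0.5 Hz) give trains of
  realistic magnitude for wide-dynamic-range neurons.
* `sim_wur_cohort()` gives each participant a log-normal true WUR
  (median 1.27, log-SD 0.27 — chosen so the cohort IQR is ≈ 0.46),
  skewed single-rating levels (median 2.85), multiplicative repeat
  noise, and a 2% outlier class with near-zero single ratings that
  produces the WUR > 6 exclusions.

What the generators do **not** emulate: biophysics (no conductance or
indicator-kinetics models), photobleaching and motion artefacts,
correlated noise across ROIs, rater drift, or genotype structure.
Passing tests therefore demonstrate that the estimators recover the
statistical structure they assume, not that real recordings satisfy
those assumptions.

## Problem sizes and numerics

The test suite and the acceptance script run at desk scale: cohorts of
~300 synthetic cells (729 for the retention summary), 500 replicate
spike-train fits, 5000 power-simulation replicates, 2000-point
Box-Cox tuning — a few seconds each. Nonlinear fits use
Levenberg–Marquardt (`minpack.lm`) with bounded parameters; AUC uses
`pracma::trapz`; ties at the reliability and WUR thresholds pass/fail
by the strict conventions stated above; degenerate inputs (flat
trains, rising decay segments, zero-variance baselines, monomorphic
genotype draws) are all defined outcomes rather than errors.

## Known limitations

* The reliability decomposition fixes one of several defensible
  estimators; scores near the threshold can differ under per-epoch
  variance averaging.
* The published headline electrophysiology values (e.g. a wild-type
  wind-up of 135.2 ± 20 spikes) depend on raw recordings and are not
  reproduced here; the pipeline instead guarantees the identities and
  recovery properties those values rely on.
* The up-down pattern constants are computed, not transcribed; for
  short ladders the estimate can differ from table look-up by a
  fraction of a step.
* Power calculations are single-SNP, quantitative-trait, additive
  only.
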