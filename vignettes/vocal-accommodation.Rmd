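---
title: "Quantifying vocal dialect accommodation: models and design choices"
author: "vocalaccom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal dialect accommodation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalaccom)
```

## The scientific problem

Captive populations of common marmosets (*Callithrix jacchus*) differ in
the acoustic structure of shared call types — they have vocal dialects.
Three explanations compete: genetic differences between populations,
acoustic adaptation to the physical environment, and social vocal
learning. Translocation designs separate them: moving animals to a new
building without changing their social surroundings tests environmental
accommodation, while moving them into acoustic range of a population with
a different dialect — without direct social contact — tests *crowd vocal
learning*, accommodation driven by passive exposure alone.

This package implements the full analysis chain such a design needs:

1. **Acoustics** — per-call parameterization of trill, phee and food
   calls (17 parameters for trills, 15 otherwise).
2. **Dimensionality reduction** — PCA on z-transformed parameters with
   Horn parallel-analysis retention.
3. **Crossed pDFA** — a permuted discriminant function analysis that asks
   whether calls differ between conditions while controlling for caller
   identity.
4. **Vocal distance** — a single per-call number: the variance-weighted
   Euclidean distance of a call from a reference population's average
   vocalization in retained-component space.
5. **Accommodation models** — mixed-effects models of log vocal distance
   over exposure time, a pre- versus post-translocation linear model, and
   bootstrapped weekly summaries.
6. **Synthetic data** — a generator with known dialect structure and
   convergence dynamics, so every stage can be validated against ground
   truth.

## Acoustic parameterization

`track_f0()` estimates the fundamental-frequency contour by short-time
normalized autocorrelation: frames of `3 / floor` seconds every 5 ms,
peak picking over the lag range corresponding to a 3–14 kHz search band
(the tonal range of marmoset calls), parabolic refinement of the peak
lag, and a voicing threshold of 0.5 on the peak correlation. Because a
periodic signal correlates equally well at every multiple of its period,
the peak search applies a small per-octave penalty (`octave_cost`,
default 0.1) that favours the shorter lag; without it, frame-level noise
makes octave-down errors essentially random. Calls in which no frame is
voiced are flagged unmeasurable and excluded, mirroring the field
practice of dropping calls that cannot be measured in full.

`extract_features()` computes, per call: F0 at call start and end, mean,
minimum and maximum F0, the percentage of the call for which F0 is at
its maximum (within 1%), the absolute F0 slope, the mean frame-to-frame
F0 variation per second, the frequency at the first, second and third
quartiles of spectral energy, the whole-call spectral peak, the
percentage of frames whose own spectral peak lies within 1% of it, local
jitter, and duration. Trills add the frequency-modulation rate and
extent of the contour. Where the literature leaves the exact definition
open, this package fixes it as follows and exposes it as a parameter:

* **F0 slope** is `|f0_end - f0_start| / duration`; **variation per
  second** is the mean absolute frame-to-frame F0 difference divided by
  the frame step.
* **Energy quartiles** come from the cumulative distribution of the
  Welch-averaged power spectrum of the whole call, with linear
  interpolation between bins.
* **Duration** is measured between the first and last frames whose
  energy is within 25 dB of the envelope peak.
* **FM rate** is the dominant frequency of the detrended F0 contour
  (zero-padded periodogram with parabolic peak refinement). **FM
  extent** defaults to twice the amplitude of a least-squares sinusoid
  fitted at that rate. The raw peak-to-trough of the contour
  (`extent_method = "extrema"`) is also available, but each cycle
  extremum is a maximum over noisy frame estimates and therefore biased
  outward at realistic signal-to-noise ratios; the sinusoid fit averages
  the tracking noise out and round-trips synthetic trills within 5% at
  20 dB SNR.

All parameters are invariant to global amplitude scaling, and unvoiced
frames never enter F0 statistics. `select_calls()` applies the
first-*k*-per-session sampling quotas (10 phee, 5 trill, 20 food by
default) after removing flagged calls, and `weekly_inclusion_filter()`
drops (caller, call type, week) cells with fewer than 5 calls — the
inclusion rule for all longitudinal analyses.

## PCA with parallel-analysis retention

Parameters are z-transformed (sample SD, constants stored for projecting
later calls), and the PCA is computed from the correlation matrix, so
eigenvalues sum to the number of parameters. Retention follows Horn's
parallel analysis: `parallel_analysis_thresholds()` simulates (by
default) 10,000 standard-normal datasets of the empirical shape and
takes the 95% quantile of each eigenvalue *rank*; components are kept as
the leading run whose eigenvalue exceeds its rank's threshold. A scalar
mode that compares every eigenvalue against the rank-1 threshold exists
because the rank-wise/scalar distinction is often left implicit in
applied write-ups; rank-wise is the default. If no component passes,
`retained_pca()` stops with an error rather than silently keeping one —
a dataset whose structure is indistinguishable from noise should not be
pushed through a distance analysis.

Loadings carry a fixed sign convention (largest-magnitude loading
positive), making repeated runs byte-identical. For the
social-accommodation analysis the model is fitted on the pooled calls of
both populations per call type and all calls are then projected; the
pooled convention keeps translocated and baseline calls in one common
space and is configurable in principle by fitting `retained_pca()` on
any subset.

## Crossed permuted DFA

The pDFA asks whether calls separate by condition once individual
identity is controlled. The observed statistic averages, over
`n_selection_rounds` balanced splits, the percentage of held-out calls
correctly classified by a pooled-covariance linear discriminant trained
on `cell_quota` calls per (individual × condition) cell. The null
distribution repeats *the same computation* on data whose condition
labels have been permuted blockwise within each individual — whole
(individual × condition) blocks are relabelled together, preserving the
non-independence of calls from the same animal. The p-value uses the
add-one convention, and the chance-expected correct classification is
the mean of the permuted statistics.

One design point deserves emphasis: the permuted statistics are averaged
over the *same* number of selection rounds as the observed one. A
cheaper convention evaluates each permutation with a single random
selection; because a single-split statistic is noisier than a
100-split average, that convention breaks exchangeability and is
markedly conservative (in our null calibration it rejected at well below
the nominal rate). The symmetric default restores exchangeability; the
single-split variant remains available through
`n_selection_rounds_null`. With the symmetric convention, the type-I
error rate at α = 0.05 over 200 null simulations falls inside the exact
binomial band around 0.05, and a condition shift of 1.5 within-individual
SD on two of four variables is detected with power above 0.9.

The discriminant core is an equal-prior Gaussian linear discriminant
with pooled within-class covariance; a singular pooled covariance falls
back to a small ridge (`1e-8 × trace / p`). Ties in the discriminant
scores break toward the first class in sorted label order.

## Vocal distance

For each call type the reference population's *average vocalization* is
a centroid in retained-component space: per axis, each baseline
individual's 10% trimmed mean of call scores, averaged across
individuals. The two-stage construction gives every individual the same
weight regardless of call count, and the trimming makes the centroid
insensitive to stray calls. The centroid is computed once from the full
baseline sample and frozen: any change in distance over time is then
attributable to the focal animals.

A call with score vector \(s\) has distance

\[ d = \sqrt{\sum_k \big(p_k\,(s_k - c_k)\big)^2}, \]

where \(p_k\) is the proportion of *total* variance (denominator = all
components, not just retained ones) explained by component \(k\). The
weighting is read as a rescaling of each axis before the Euclidean norm;
the alternative reading with the proportions inside the squares
(`method = "sqrt"`) is provided for sensitivity analysis, and the two
differ only by a per-axis monotone rescaling. All models work with
\(\ln d\); an exact zero distance (a probability-zero event) is clamped
at `1e-12` with a warning.

## Accommodation models

`fit_accommodation()` fits, by maximum likelihood,

```
ln_distance ~ sex + week + sex:week + (1 | caller)
```

with females as the reference sex and weeks coded 0 (natal colony),
0.5 (quarantine) and 1–16 (weeks of passive exposure). The quarantine
anchor rows are included: they pin down the pre-exposure distance.
Fixed-effect p-values use Satterthwaite degrees of freedom. When the
interaction is not significant at 0.05 the model is refitted without it
and the reduced fit is reported — the convention of interpreting only
the highest-order term in which a predictor appears. Random effects are
a per-caller intercept only: with four translocated individuals, random
slopes are not estimable with any reliability, though the underlying
`lmer` interface accepts them if a user supplies more animals.

Each fit carries a likelihood-ratio test against the
intercept-plus-random-effects null (both by ML on identical rows) and
marginal/conditional R²: with \(\sigma_f^2\) the variance of the
fixed-effect predictor, \(\sigma_u^2\) the random-intercept variance and
\(\sigma_e^2\) the residual variance,
\(R^2_m = \sigma_f^2 / (\sigma_f^2+\sigma_u^2+\sigma_e^2)\) and
\(R^2_c = (\sigma_f^2+\sigma_u^2) / (\sigma_f^2+\sigma_u^2+\sigma_e^2)\).

`compare_prepost()` contrasts the recordings immediately before the
second translocation (quarantine, week 0.5) with recordings made five or
more weeks after it, by which time transient environmental effects have
decayed; the model is `ln_distance ~ condition * sex`, reduced to the
additive model when the interaction is not significant, and the headline
effect is the post-minus-pre contrast averaged over the sexes.
`weekly_bootstrap_summary()` produces per-(caller, week) means of
\(\ln d\) with percentile bootstrap 95% intervals over calls, for cells
passing the 5-call rule — the plot-ready trajectory data.

## The synthetic-data generator

`simulate_features()` draws one row per call from

\[ x = \delta_{ct}\,g(w) + \pi_{ct}\,\mathbf{1}[w \in W_p] + u_{i} +
   \epsilon, \]

with \(\delta_{ct}\) the dialect offset of the translocated colony for
call type *ct* (zero for the target colony), \(g(w) = e^{-r\,w}\) for
exposure weeks and \(g = 1\) at weeks 0 and 0.5 (the quarantine offers a
new environment but no novel vocal input, so the natal dialect is
inherited unchanged), \(\pi\) a transient perturbation active only in
the first week after a translocation, \(u_i\) a per-individual offset
drawn once (the random-intercept structure the mixed model assumes), and
\(\epsilon\) within-call noise. The exponential convergence shape is
smooth, monotone, and makes expected log distance approximately linear
in exposure time — the form the accommodation model fits.

Within-call noise is *not* independent across parameters: real acoustic
measures are strongly correlated (the F0 statistics move together, as do
the spectral energy quartiles). The generator therefore draws noise from
a latent factor model — four shared factors carrying 60% of the per
-parameter variance by default — which reproduces two empirical features
of such data: parallel analysis retains a handful of components, and the
retained set explains on the order of two-thirds of total variance.
Dialect offsets are placed *inside* that correlated subspace
(`factor_aligned_offset()`): a shift confined to directions the PCA
discards would be invisible downstream, which real dialect differences
are not. Offset magnitudes are free parameters (the source study does
not report them in parameter units); the defaults are set so each call
type's direction of change is recoverable at the simulated sample sizes
— trills and phees converge (males faster than females for trills), food
calls diverge slightly.

Three scenario constructors cover the designs: `default_scenario()`
(two colonies × 4 individuals, weeks 0 / 0.5 / 1–16),
`experiment1_scenario()` (one colony of eight, six males and two
females, conditions Before / After1 / After2 with a transient
perturbation that affects food calls strongly, phee calls weakly and
trills not at all), and `slope_recovery_scenario()` (below).
`synthesize_waveform()` additionally produces audio test signals — pure
tones, linear chirps and sinusoidally modulated trills with additive
noise — sufficient to validate the tracker and feature definitions by
round-trip, though it makes no attempt to imitate real marmoset
spectrograms beyond tonal/FM structure, and compound calls are out of
scope.

What the generator does *not* emulate: session-level autocorrelation,
caller misidentification, unbalanced recording effort, drifting
recording conditions, or any spectro-temporal detail of real calls.
Passing validation therefore demonstrates that the statistical machinery
is correct and calibrated under its own assumptions — not that those
assumptions hold for any particular empirical dataset.

## The slope-recovery scenario and its calibration

`slope_recovery_scenario()` is the package's parameter-recovery
benchmark: a single call type with equal convergence rates for both
sexes, chosen so the expected log vocal distance declines by 0.05 per
exposure week, a magnitude representative of reported
dialect-accommodation effects in captive marmosets. Three of its
settings are deliberate:

* **Offset magnitude 4 within-call SD on eight parameters.** The log
  distance of a decaying signal flattens once the signal approaches the
  noise floor of the distance (the norm of the weighted per-call noise).
  At this magnitude the trajectory stays signal-dominated through week
  16 and replicate runs put the realized slope within half a standard
  error of the target, so the generative rate needs no correction
  factor. Note that z-scaling bounds how large the separation can be
  made in standardized units — beyond a point, larger raw offsets only
  inflate the parameter variances they are measured against.
* **Small between-individual variation** (`individual_sd` well below the
  call SD). Per-individual offsets displace each animal's distance
  trajectory and its noise floor, creating slope heterogeneity that a
  random-intercept model does not propagate into the slope's standard
  error; keeping it small keeps the nominal confidence interval honest.
* **Information-balanced recording effort.** The variance of log
  distance grows as the signal decays (later weeks sit closer to the
  distance's noise floor), which a homoscedastic mixed model
  underweights exactly where leverage on the slope is highest — its
  standard error is then slightly too small and interval coverage drops
  below nominal. The benchmark therefore allocates calls the way a
  recovery experiment should: two natal-colony and two quarantine anchor
  blocks, then weekly targets rising from 5 (the weekly-inclusion
  minimum) to 21 across the sixteen exposure weeks, so each week
  contributes a comparable amount of information about the slope and the
  nominal confidence interval is honest. This residual-variance growth
  is a genuine property of distance-to-centroid outcomes under
  convergence and is worth remembering when interpreting confidence
  intervals from such models on real data, where recording effort is
  rarely balanced this way.

## Numerical choices

* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; nothing depends on or mutates the global stream.
* Parallel-analysis thresholds, permutation p-values and bootstrap
  intervals are deterministic given their seed.
* PCA loading signs are fixed by the largest-magnitude-positive rule.
* Eigenvalue/threshold comparisons are strict (`>`); retention stops at
  the first non-exceeding rank.
* The discriminant's ridge fallback (`1e-8 × trace / p`) only engages on
  a singular pooled covariance and is reported via a message.
* Exact-zero distances are clamped at `1e-12` before the log.
* The validation suite runs at reduced but statistically meaningful
  problem sizes: 200 null and 100 power replicates with 500 permutations
  and 5 selection rounds for the pDFA calibration; 100 replicates per
  rank for retention; 100 end-to-end replicates for slope recovery; 500
  replicates for the likelihood-ratio-test calibration. Those sizes are
  the package's choices for routine validation; all of them scale up by
  changing one argument.

## Known limitations

* The acoustic tracker is designed for tonal, high-F0 calls in quiet
  recordings; it is not a general pitch tracker and has no voicing model
  beyond the correlation threshold.
* The pDFA implements the crossed design only (control factor crossed
  with the test factor); nested designs are an extension point.
* With four focal animals, sex effects and family effects are
  confounded in the study design this package mirrors; the models
  estimate the sex terms but cannot disentangle that confound.
* Likelihood-ratio tests involving between-individual terms (sex) rely
  on asymptotics in the number of animals: their chi-square reference is
  well calibrated in our null simulations with a dozen individuals but
  cannot be trusted for the four-animal design itself.
* Confidence intervals from the homoscedastic LME are mildly
  anticonservative when distances traverse a wide signal-to-noise range
  (see the slope-recovery section); users fitting real data with strong
  convergence may wish to compare against heteroscedasticity-robust
  checks.
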