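# vocalaccom

Quantitative analysis of **vocal dialect accommodation** in animal call
recordings, built around translocation study designs in common marmosets
(*Callithrix jacchus*). The package is aimed at bioacousticians and
quantitative behavioural ecologists who need to ask: after animals are
moved into acoustic contact with a population that has a different
dialect, do their calls drift toward it — and at what rate?

## What it computes

The analysis chain has five stages, each exposed as a fitting function
returning a classed object with `print`/`summary`/`coef`/`predict`
methods where they apply:

1. **Acoustic parameterization** (`track_f0()`, `extract_features()`):
   autocorrelation F0 tracking (3–14 kHz search band, octave-cost peak
   selection) and the per-call parameter set used for marmoset calls —
   F0 start/end/mean/min/max, % of call at maximal F0, F0 slope and
   variation, spectral energy quartiles, peak frequency and its
   persistence, jitter, duration, plus FM rate and extent for trills
   (17 parameters for trills, 15 for phee and food calls).
2. **Dimensionality reduction** (`retained_pca()`): PCA on z-transformed
   parameters with Horn parallel-analysis retention — keep the leading
   components whose eigenvalues exceed the 95% quantile of eigenvalues
   from (by default) 10,000 random datasets of the same shape.
3. **Crossed permuted DFA** (`crossed_pdfa()`): does call structure
   differ between conditions once caller identity is controlled? The
   observed statistic is the mean held-out cross-classification accuracy
   of a pooled-covariance linear discriminant over balanced training
   selections; the null permutes condition labels *blockwise within each
   individual*; `p = (#{null >= observed} + 1) / (n_perm + 1)`.
4. **Vocal distance** (`population_centroid()`, `weighted_distance()`,
   `build_distance_records()`): each call's distance from the reference
   population's average vocalization in retained-component space,

   `d = sqrt( sum_k ( p_k (s_k − c_k) )² )`

   where `p_k` is component *k*'s proportion of total variance, `s` the
   call's scores, and `c` the centroid — the across-individual mean of
   per-individual 10% trimmed means, computed once from the baseline
   sample and frozen.
5. **Accommodation models** (`fit_accommodation()`,
   `compare_prepost()`, `weekly_bootstrap_summary()`): maximum-likelihood
   LME `ln d ~ sex * week + (1 | caller)` (interaction dropped when not
   significant), likelihood-ratio test against the intercept+random
   null, marginal/conditional R², a pre- vs 5+-weeks linear model, and
   bootstrapped weekly means.

`run_experiment1()` (environmental accommodation: Before/After1/After2
pDFAs) and `run_experiment2()` (social accommodation: distances and
models over 16 exposure weeks) orchestrate the stages end to end.

A first-class **synthetic-data module** (`default_scenario()`,
`simulate_features()`, `synthesize_waveform()`) generates feature tables
— and audio test signals — with known dialect offsets, individual random
effects, factor-correlated call noise, a weekly recording schedule and
per-call-type convergence/divergence dynamics, so every stage is
validated against ground truth.

## Worked example

Simulate the default two-colony scenario (four translocated "MA"
animals, four baseline "ZH" animals; trills and phees converge, food
calls diverge) and run the social-accommodation analysis:

```r
library(vocalaccom)
scen <- default_scenario()
sim  <- simulate_features(scen, seed = 20)
rep2 <- run_experiment2(sim$features, pa_iter = 2000, n_boot = 500, seed = 20)
print(rep2)
```

Output for the trill stage (phee and food follow):

```
-- trill: 5 components retained (71.2% of variance) --
Accommodation LME [trill] (ML): ln vocal distance ~ sex + week
  (Intercept)    B =  -0.1524  SE = 0.0471  t =  -3.235  P = 0.01553 *
  sexM           B =  -0.2376  SE = 0.0587  t =  -4.045  P = 0.01554 *
  week           B =  -0.0237  SE = 0.0031  t =  -7.689  P = 6.026e-14 *
  N = 608 calls from 4 individuals
  R2m = 0.157, R2c = 0.170; LRT chi2(2) = 62.918, p = 2.175e-14
Pre/post comparison [trill]: 64 pre, 384 post calls
  condition effect (post - pre, sexes averaged): -0.2531
  condition p = 5.703e-06 *; interaction dropped
```

Reading it: the PCA retained five components carrying 71% of parameter
variance; log vocal distance to the baseline-colony centroid declines by
0.024 per exposure week (the convergence signal), males sit closer than
females, the model beats the intercept-only null decisively, and calls
recorded 5+ weeks after translocation are significantly closer to the
new population than the quarantine recordings immediately before it
(−0.25 log units). The food-call stage of the same run shows the
opposite, divergent sign (`week B = +0.0127`), as simulated.

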