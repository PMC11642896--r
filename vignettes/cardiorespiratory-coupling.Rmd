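---
title: "Cardiorespiratory coupling features and health-status classification: models and methods"
author: "crcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory coupling features and health-status classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Short static cardiorespiratory recordings — a few minutes of supine
breathing with simultaneous RR-interval and respiration (impedance
pneumography, relative tidal volume) acquisition — carry enough information
to distinguish pediatric cardiac patients, healthy children and trained
adolescent athletes. Classic heart-rate-variability (HRV) features describe
the RR series alone; the package's central premise is that *directional
cardiorespiratory coupling* (CRC) features — how strongly respiration
drives the heart rhythm (respiratory sinus arrhythmia, RSA) and vice versa
— add diagnostic information that univariate features cannot express, and
that this shows up as a measurable gain in classification accuracy.

The package implements the whole pipeline: a calibrated synthetic cohort
generator (the original clinical data are not public), signal
preprocessing, a 157-feature battery, SMOTE-balanced cross-validated
multi-model comparison, and Shapley/permutation-importance explainability
driving a reduced feature set.

## The synthetic cohort generator

Each synthetic subject is a pair (respiration waveform at 250 Hz,
RR-interval sequence in ms) plus demographics and a group label.

**Respiration.** Built breath by breath: per-breath instantaneous rate is
drawn from a truncated normal (3–40 breaths/min, matching the analysis
band), inspiration and expiration are half-cosines in the preset
inspiration:expiration ratio (default 0.8), and per-breath amplitude is
jittered (15% CV). The preset respiratory-rate SD is interpreted as the
*between-subject* spread — the group descriptive statistics it is taken
from are across-subject summaries — while within-recording breath-to-breath
jitter is 0.3 of that SD (≈6% CV, within the range of resting
breath-to-breath variability). Drawing per-breath rates at the full
between-subject SD would bias the detected rate (60/mean breath duration, a
harmonic-type mean) about 4% low.

**RR intervals.** The RSA mechanism is the simplest model with tunable
directional coupling:

$$RR_n = \mu_{RR} + a\,v_n + g\,r(t_n - \ell),$$

where $\mu_{RR} = 60000/\mathrm{HR}$ ms, $v$ is a unit-variance AR(1)
process (coefficient $\phi$, default 0.9 — slow "autonomic" variability),
$r$ is the unit-variance respiration value at the lagged beat time
($\ell$ = 0.4 s by default, inside the ±1 s physiological window), and
beat times accumulate as $t_{n+1} = t_n + RR_n/1000$. Respiration drives
RR and not conversely, so the ground-truth causal direction is known.

**Calibration.** Writing $c$ for the coupling strength (the fraction of RR
variance of respiratory origin) and $T$ for the total RR variance,
$g^2 = cT$ and $a^2 = (1-c)T$; $T$ follows from the RMSSD target via
$\mathrm{RMSSD}^2 = 2T[(1-c)(1-\phi) + c(1-\rho)]$, with $\rho$ the
respiration autocorrelation at a lag of one mean RR interval, estimated
from the subject's own waveform. `calibratePreset()` then runs a pilot
Monte-Carlo (100 recordings) and rescales $(a, g)$ by a single factor so
realized mean RMSSD hits the target; the scale factor preserves the
variance share exactly. Degenerate cases are exact: $c = 0$ gives $g = 0$,
$c = 1$ gives $a = 0$.

**Cohorts.** Subject-level heart rate, RMSSD, respiratory rate and
demographics (age, mass, height; sex as group-ratio Bernoulli; BMI
computed) are drawn from truncated normals matched to the group
descriptive statistics, with two refinements:

* *Mean recalibration.* The printed ranges are asymmetric around the
  printed means (e.g. RMSSD 68.2, range 5.6–178.9), so a truncated normal
  centred at the printed mean has a truncated mean up to 10% higher. The
  pre-truncation location is solved so the *truncated* mean equals the
  printed mean.
* *Stratified draws.* Subject draws use randomized stratified inverse-CDF
  sampling: the marginal stays the truncated normal, but the cohort-mean
  error is $O(1/n)$ rather than $O(1/\sqrt n)$. Without it, the ±5%
  RMSSD-recovery check at $n = 500$ would be only ≈2 standard errors wide —
  a coin flip dressed up as a test.

The default group presets (Cardiac / Healthy / Sport) pin heart rate
(72.8/79.4/76.9 bpm), RMSSD (55.3/61.8/68.2 ms) and respiratory rate
(18.5/18.8/17.1 breaths/min) with their SDs and ranges to the study
population's descriptive statistics. The coupling strengths (0.2/0.5/0.7)
are *separability knobs*, not physiological estimates: no ground truth for
per-group coupling exists, so they are free, documented parameters.
`generateCohort(arPhiRange =)` optionally draws each subject's intrinsic
AR(1) coefficient from a range, emulating heterogeneous autonomic dynamics.

What the generator does **not** emulate: ectopic beats and artifacts (the
source recordings were physician-corrected), nonstationary drifts, age
dependence of HRV, within-group clinical heterogeneity, or any real
relationship between demographics and physiology (demographics are drawn
independently of the signals). Passing tests therefore demonstrate that the
*pipeline* behaves correctly under controlled coupling, not that it
reproduces clinical effect sizes.

## Preprocessing

* Respiration band-pass 0.05–0.67 Hz (3–40 breaths/min), zero-phase.
  The band-pass is realized as a cascade of a 2nd-order Butterworth
  high-pass and a 4th-order low-pass, each applied forward–backward: a
  direct transfer-function band-pass with a 0.05 Hz corner at 250 Hz
  sampling is numerically unstable (the polynomial roots collapse), while
  the cascade is well conditioned. Zero phase matters because the coupling
  features are lag-sensitive. Measured response: gain 0.998 at 0.30 Hz,
  ≈0.0016 at 0.01 Hz and 1.5 Hz.
* RR stationarity is checked with the Phillips–Perron unit-root test
  (`stats::PP.test`, default lag truncation); the result is logged, not
  fatal; constant series are flagged degenerate.
* The tachogram interpolates (beat time, RR) pairs with a cubic spline on
  a uniform grid at the respiration sampling rate, spanning first to last
  beat (no extrapolation).
* Both signals are decimated to 25 Hz (8th-order Chebyshev anti-alias,
  zero-phase, mean-preserving) for the coupling features.

## The 157-feature battery

5 demographic + 102 cardiac + 18 respiratory + 32 causal/information
features; `featureManifest()` is the normative list. The full cardiac
identity list in the source material is not reproducible from its main
text, so the battery fills the standard HRV categories to the printed
count: 36 time-domain, 14 frequency-domain (Welch, 120 s Hann segments,
50% overlap, on a 4 Hz resampled tachogram; VLF/LF/HF/VHF bands), 27
Poincaré/asymmetry/fragmentation, 19 complexity (sample/approximate/fuzzy/
permutation entropies, multiscale entropy at scales 1–6, DFA α1/α2,
Lempel–Ziv, Katz fractal dimension, PRSA acceleration/deceleration
capacity), 6 symbolic-dynamics (6 bins over μ±2σ, 3-symbol words classified
0V/1V/2LV/2UV, word-distribution entropies).

Respiratory features come from trough–peak–trough breath segmentation with
a 1.5 s minimum duration and a 0.1×median amplitude floor; tidal volume is
uncalibrated, so amplitudes are *relative* (indexed by the median breath
amplitude — the median relative TV is 1 by construction).

## Coupling features and the analysis grid

The causal block computes, in both directions: linear Granger causality
(GC, the log ratio of restricted vs full autoregression residual variances,
OLS, 1/(n−k) normalization), a beat-aligned linear GC variant (RR sequence
vs respiration sampled at beat times), kernel GC (ridge regression on
Gaussian-RBF activations of deterministically chosen centers; approaches
linear GC on linear data as the kernel widens), large-scale nonlinear GC
(k-means clustered delay embedding of the source, row-normalized RBF
activations appended to the target autoregression, F-statistic and RSS
affinity), ML GC (MLP with 16 hidden units and degree-2 polynomial,
held-out 30% tail), and transfer entropy (equal-frequency binning, 4 bins,
lags 1–2, 20-shuffle baseline subtraction). The information block adds
mutual information at lag 0 and its lagged maximum, Pearson correlation at
lag 0, the maximal-|r| lagged correlation within ±1 s (signed, ties toward
lag 0), signal/joint/conditional entropies, and cross sample/approximate
entropies.

**Why a 5 Hz analysis grid.** The cubic-interpolated tachogram is extremely
smooth; at 25 Hz its one-step linear prediction residual collapses to
~10⁻⁵ of the signal variance and the GC log-ratio becomes a ratio of
numerical noise: measured GC stays between 0.6 and 1.0 with *zero* true
coupling and does not respond to coupling strength. Decimating the pair to
5 Hz and selecting the order by BIC over 1–5 lags (the same ±1 s window)
restores textbook behavior: GC ≈ 0 for uncoupled pairs and strictly
monotone cohort means across coupling 0 → 0.8 for every directional
estimator. The grid is configurable (`couplingControl(fsAnalysis =)`).
Correlation, MI and entropy features are not ratio-of-residual statistics
and stay on the 25 Hz grid.

**Surrogate-referenced ML GC.** A naive ln(MSE_restricted/MSE_full) with a
finite MLP is biased negative under independence: the full model wastes
capacity on useless inputs and pays for it on held-out data (measured mean
≈ −0.09). The implementation instead feeds the *same* architecture a
circularly time-shifted surrogate of the source as the restricted
reference; capacity and optimizer effects cancel and the null is centred
at 0.

**Sign conventions.** Finite-sample-negative causality estimates are
clipped to 0 in the feature vector (raw values are kept in the attached
computation log); GC ratios are masked when the denominator is ≤ 10⁻⁸.

A note on direction: on this generator the beat-aligned GC is strongly
direction-specific (Resp→RR ≫ RR→Resp). Grid-based GC on interpolated
tachograms is less so, because the spline at time *t* uses beats after
*t* — a small, structural anticipation that inflates the reverse
direction. The same artifact plausibly affects any pipeline that
interpolates tachograms before causal analysis and is one reason reverse
(RR→Resp) features can rank highly in practice.

## Modeling and evaluation

Datasets D1–D6 are column subsets of the feature table: D1 =
demographic+cardiac, D2 = D1+respiratory, D3 = D2+causal/information, D4 =
D3 minus demographics, D5/D6 = the 35 most influential features of D3/D4 by
pooled |Shapley|. Cross-validation is stratified 10-fold (stratification
guarantees every class in every test fold at these cohort sizes); within
each training fold, in order: median imputation (fit on train), SMOTE
upsampling to the strategy counts (default 200/200/200; synthetic points
are convex combinations of same-class nearest neighbors; originals
preserved), and standardization (fit on train). Test folds are untouched —
no synthetic row, imputation statistic or scale parameter ever comes from
test data.

The model zoo: logistic regression (plain, ridge, lasso), decision tree,
RBF SVM, random forest, gradient boosting and a second boosted-trees
configuration (both via xgboost: shallow/slow vs deep/regularized),
naïve Bayes, k-NN, AdaBoost (SAMME over stumps — no dedicated package is
available in the target environment), and a 16-unit MLP. Hyperparameters
are fixed, documented defaults rather than searched: at these cohort sizes
a search costs more variance than it removes, and the package's scientific
claims are about feature sets, not tuning.

Metrics per fold: accuracy; macro-averaged precision, recall and F1
(2TP/(2TP+FN+FP) — the standard form); the multiclass Matthews correlation
coefficient
$(n\,c - \sum_k p_k t_k)/\sqrt{(n^2-\sum p_k^2)(n^2-\sum t_k^2)}$ with a
guarded zero denominator; and one-vs-rest macro AUC (rank-based). Datasets
are compared by two-sided paired Wilcoxon signed-rank tests on the 10 fold
values (α = 0.05, no multiplicity correction); the best model per dataset
is the one with the highest mean accuracy.

## Explainability and selection

Shapley attributions use permutation sampling with every sampled feature
ordering walked against the whole (≤100-row) background set; the estimator
is exact for additive models and each path telescopes, so
$\sum_j \phi_j(x) + \text{baseline} = f(x)$ holds to numerical precision.
Permutation variable importance uses the 1−AUC dropout loss per class
(one-vs-rest), 30 rounds by default. Feature selection ranks by mean
|Shapley| pooled over samples, folds and classes (ties broken
alphabetically for determinism) and keeps the top 35.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen to give stable statistics on a
single core: calibration-recovery cohorts of 500 recordings per group,
coupling-monotonicity cohorts of 50 recordings at each of four coupling
levels, and a 60-subject cohort (20 per group, couplings 0.25/0.45/0.65,
per-subject AR coefficients from 0.3–0.95) for the dataset-comparison
property that adding causal/information features (D3) significantly
outperforms the respiratory+cardiac set (D2) under paired Wilcoxon. The
last design deserves a remark: with homogeneous intrinsic dynamics the RSA
variance share is recoverable from the RR spectrum alone and D2 saturates;
heterogeneous AR coefficients are what make "groups differ only in
coupling" true in the univariate view as well.

## Known limitations

* The cardiac feature identities beyond the named standards are pinned by
  this package, not by the source material; counts, not identities, are
  the hard constraint.
* Grid-based GC on interpolated tachograms carries the spline-anticipation
  artifact described above; the beat-aligned variant is provided for a
  clean directional read-out.
* The generator's coupling levels are synthesis knobs; classification
  accuracies on synthetic cohorts are not comparable to clinical values.
* kernel GC and lsNGC hyperparameters (centers, widths) follow documented
  defaults; they are configurable but not tuned.
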