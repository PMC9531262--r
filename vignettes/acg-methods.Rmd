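---
title: "Methods: simulating and analysing multifrequency transcranial ultrasound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing multifrequency transcranial ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acgtools)
```

## Background

Acoustocerebrography (ACG) probes the brain with ultrasound pulses at several
carrier frequencies (here 10 channels spanning 0.5–2.5 MHz) transmitted
across the skull. Because the bulk modulus of brain tissue is nonlinear and
frequency dependent (the Kramers–Kronig relations link dispersion and
absorption), each frequency component travels at its own speed and loses its
own share of energy. A measurement therefore yields, per frequency channel,
a time series of the relative **time of flight** (TOF, µs) and of the
**attenuation** (ATT, dB).

The working hypothesis of ACG monitoring in critical illness is that a
healthy brain keeps these frequency channels nearly synchronous, while acute
dysfunction — such as sepsis-associated encephalopathy (SAE), with its edema
and microcirculatory impairment — decouples them. `acgtools` implements the
two analysis routes built on that hypothesis, together with a synthetic
cohort generator that gives the methods a planted ground truth, since no
patient-level ACG recordings are publicly available.

## The dimensionality statistic

For a `T × F` matrix of channel series, the columns are mean-centered and a
singular value decomposition taken; squared singular values normalised to
explained-variance fractions give the profile $p_1 \ge p_2 \ge \dots$ The
**dimensionality** at threshold $\tau$ is

$$d_\tau = \min\Big\{k : \sum_{i \le k} p_i \ge \tau\Big\},$$

an integer between 1 (one linear combination explains everything — perfect
synchrony) and $F$ (every channel has its own dynamic). Choices worth
stating:

* **Centering, no scaling.** Columns are mean-centered so "explained
  variance" is well defined, but not variance-scaled: relative channel
  amplitudes are part of the signal.
* **Threshold.** The default is $\tau = 0.90$, with $\tau = 0.95$ the
  conventional stricter alternative; both are exposed.
* **Tie handling.** The cumulative comparison uses `>=` with an absolute
  tolerance of `1e-12`, so the count does not depend on the linear-algebra
  backend's last bits.
* **Degenerate input.** An all-constant matrix has no variance to explain;
  its profile is defined as $(1, 0, \dots)$ with a warning, giving
  dimensionality 1.
* **Granularity.** Dimensionality is computed per single measurement and
  averaged per patient-day (`patient_day_dimensionality()` returns both),
  matching the convention that patient-level results are session averages.
  Computing it across a stacked session is possible by binding matrices, but
  the per-measurement route is the default because probe repositioning
  between single measurements changes baselines.

## The feature table

The genetic algorithm selects from a deterministic vocabulary of 1,010
per-patient-day features (`acg_feature_names()`): per-channel summary
statistics (location, spread, trend, autocorrelation, roughness), pairwise
within-modality channel comparisons (correlations, also of the differenced
series, and mean/SD/IQR contrasts), cross-modality TOF–ATT correlations,
products and ratios, spectral slopes across the band, and the PCA summaries
themselves. The vocabulary was chosen to (a) exceed 1,000 columns at the
default grid, (b) contain the two families that matter for the scientific
story — attenuation-based values and TOF×ATT interactions — and (c) be cheap
and fully deterministic. Features are computed per single measurement and
averaged over the session's 10 measurements, so a patient-day row is the
arithmetic mean of its measurement-level rows.

Before any PCA-based scoring the table is z-scored per column
(`standardize_features()`), so that the first principal component of a
feature subset is invariant to feature units; constant columns map to zeros.

## Genetic-algorithm feature selection

An individual is a feature subset of size at most 15; fitness is the
absolute Pearson correlation between the first principal component of the
selected (standardized) submatrix and a clinical target. The evolution
follows the reference protocol: population 1,000; top 2% mated; a shared
feature always passes to the child, a disputed one with probability ½;
obligate mutation; 200 generations. Parameters the protocol leaves open are
fixed as defaults and exposed in `ga_config()`:

* **Mutation rates.** `p_add = 0.002` per absent feature (about two
  expected additions per individual at P ≈ 1,200) and `p_delete = 0.05` per
  selected feature.
* **Elite pairing.** Parents are drawn uniformly with replacement from the
  elite. Children fill half the population (`child_fraction = 0.5`); the
  rest is refilled with fresh random individuals, which keeps exploration
  pressure high.
* **Elitism.** `elitism_copy = TRUE` copies the elite unmutated, making the
  per-generation best fitness non-decreasing (used by the tests). This
  deviates from strictly obligate mutation, so it is a flag.
* **Stopping.** A fixed generation budget, with an optional early stop
  (no gain above `1e-4` for 30 generations) since "no significant
  improvement" is not a formal criterion.
* **Degenerate subsets.** A zero-variance submatrix scores 0; empty subsets
  arising in crossover/mutation are repaired with one uniform feature.
* **Pearson on raw targets.** Fitness correlates PC1 with the raw clinical
  values (not ranks), consistent with the Pearson correlations reported
  elsewhere in the analysis.

## Classification and evaluation

Patient-days are labelled positive when ICDSC ≥ 3 or SOFA ≥ 3
(`label_positive()`). The classifier is a support-vector machine on the
GA-derived components with stratified fivefold cross-validation. Open
choices, fixed as defaults:

* **Kernel and cost.** Linear kernel, `C = 1`; RBF behind a flag. The
  components are low-dimensional and near-linearly separable, so a linear
  margin is the parsimonious choice.
* **Grouped folds.** Folds are assigned at patient level by default
  (`group_by_patient = TRUE`): a patient's days never straddle the
  train/test boundary, avoiding identity leakage. Row-level stratified folds
  remain available, since the original protocol is ambiguous on this point.
* **Class weights.** Classes are weighted inversely to their training
  frequency. Positive labels dominate a screening cohort in which every
  septic day scores SOFA ≥ 3; without weighting the maximum-margin fit can
  collapse onto the majority class and report no specificity at all.
* **Undefined ratios.** A fold whose test part lacks a class reports `NA`
  sensitivity or specificity, excluded from the fold averages with a note.
* **ROC.** Thresholds sweep the distinct decision values; the trapezoid
  AUC equals the Mann–Whitney U statistic normalised by
  $n_+ n_-$ — an identity the tests verify to `1e-9`.
* **Per-patient verdicts.** The secondary classifier trains on the first
  half of the patients (enrollment order, groups interleaved) at
  measurement level; k-means (k = 2) summarises the unsupervised cluster
  structure, the SVM predicts, and a test patient is *correct* / *wrong* /
  *undecided* according to whether all, none, or some of its measurement
  predictions match its labels.

## Statistical report

Group comparisons report medians with 0.25–0.75 quartiles
(linear-interpolation quantiles, R type 7), the Kruskal–Wallis test followed
by the Mann–Whitney U test (exact where sample sizes permit and ties allow,
normal approximation with tie correction otherwise), and the chi-squared
test for CAM-ICU rates. No multiple-testing correction is applied by
default, matching the exploratory reporting convention; Holm is available.
The correlation table reports absolute Pearson correlations of each clinical
parameter against (a) the dimensionality summary — the mean of the TOF and
ATT dimensionality, with per-modality columns also emitted, since the
original analysis does not say which was used — and (b) the PC1 of the GA
subset selected for that parameter, pooled over all measured days by
default.

## The synthetic cohort generator

No generative model for ACG data is published, so the generator makes the
sync/desync mechanism literal. One single measurement draws each channel as

$$x_f(t) = \mathrm{baseline}(f) + \lambda_f\, z(t) + s\, \eta\, \epsilon_f(t) + \text{white noise},$$

with $z$ a shared smooth latent series (standardized AR(1),
coefficient 0.9), $\lambda_f$ an affine loading profile across the band,
$\epsilon_f$ independent smooth series per channel, $s \in [0,1]$ the latent
severity and $\eta$ the desynchronization amplitude at full severity. At
$s = 0$ with zero sensor noise the channels are affine images of one series:
dimensionality is exactly 1 by construction. Severity both desynchronises
the channels and shifts the medium: the attenuation slope grows by 35% and
the dispersion slope by 15% at full severity, mirroring the edema mechanism
by which higher frequencies are absorbed more strongly while TOF changes
little.

Study-design constants are fixed by the emulated protocol: 10 septic (SG)
and 10 control (CG) patients, SG measured on days 1, 3, 7, 14 and CG on
days 1 and 3, sessions of 10 single measurements, recording quality drawn
from a Normal(80.9, 14.6) truncated to [0, 100]%. Severities are drawn
Beta(5, 2) for SG and Beta(1.2, 8) for CG. Clinical links are linear in
severity with Gaussian noise — SOFA = clip(round(2 + 12·s)),
ICDSC = clip(round(1 + 5·s)) with controls fixed at 0 — and the laboratory
values (lactate, procalcitonin, creatinine, bilirubin) are log-normal with
location increasing in severity, calibrated to reproduce the direction and
rough magnitude of the published group differences, not their exact medians.
CAM-ICU is derived as ICDSC ≥ 4, the standard delirium cut-off, with
septic-group inclusion requiring delirium (day-1 ICDSC clamped to ≥ 4).
Severity decays exponentially after inclusion with a half-life of 2 days
for controls (postoperative recovery; their SOFA median falls from about 3
to about 2 by day 3) and 14 days for septic patients. `t_samples`
defaults to 256 per single measurement; the sampling count of the original
recordings is not reported, and none of the statistics depend on it beyond
estimation noise.

What the generator does **not** emulate: waveform-level physics (pulse
shapes, matched filtering), probe-placement artifacts beyond white noise,
within-day clinical dynamics, missing data, or any real laboratory
covariance structure. Passing tests therefore show that the analysis
recovers structure *of the kind the mechanism hypothesises*, at effect
sizes chosen here — not that it would do so on real recordings.

## Problem sizes and reproducibility

All randomness flows through explicit seeds: the cohort generator takes a
seed, `ga_config()` carries one, fold assignment takes one, and
`pipeline_config()` derives fixed per-stage offsets from a master seed, so a
pipeline run is reproducible artifact-for-artifact (the tests compare MD5
hashes). The test-suite problem sizes are chosen to exercise each claim at
desk scale: oracle checks use 100 SVD-composed matrices and 1,000 random
matrices; GA-versus-enumeration uses 20 twelve-feature tables (population
100, 30 generations); planted-feature recovery uses N = 60, P = 1,200 tables
with three planted columns sharing a latent factor (population 300, 60
generations) — the shared factor gives the subset a dominant principal
direction, which is what PC1-correlation fitness can see; end-to-end
classification averages 10 pipeline seeds at the default cohort size; and
structural cohort checks run 50 seeds with shortened series, since session
structure and score links do not depend on the series length.

## Known limitations

* The generator's severity is one latent scalar; real SAE involves several
  partially independent processes, and the high GA correlations on
  synthetic cohorts (≈ 0.8–0.96) are accordingly optimistic relative to the
  0.66–0.82 band reported on real data.
* With 20 patients, grouped fivefold cross-validation leaves few negatives
  per fold; specificity estimates are noisy and occasionally undefined in a
  fold.
* The GA is a stochastic search; determinism holds for a fixed seed but
  different seeds can select different, near-equivalent subsets when
  features are strongly correlated.
* The per-patient first-half/last-half classifier needs measurement-level
  components, which are noisier than session averages; verdicts should be
  read as a robustness probe, not a primary endpoint.
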