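# acgtools

Simulation and analysis of **acoustocerebrography (ACG)** data:
multifrequency transcranial ultrasound for monitoring acute brain
dysfunction in critical care.

ACG transmits ultrasound pulses at several carrier frequencies (10
channels, 0.5–2.5 MHz) through the skull and records, per frequency, the
relative **time of flight** (TOF, µs) and **attenuation** (ATT, dB) over
time. Because wave speed and absorption in brain tissue are frequency
dependent, acute dysfunction — e.g. sepsis-associated encephalopathy, with
its edema and microcirculatory impairment — is hypothesised to
*desynchronise* the frequency channels. `acgtools` is aimed at
biostatisticians and methods researchers who want a tested, reproducible
implementation of that analysis chain, with a synthetic cohort generator
standing in for clinical recordings that are not publicly available.

The package implements:

* **Dimensionality statistic.** For a `T × F` channel matrix with
  explained-variance fractions `p₁ ≥ p₂ ≥ …` (PCA via SVD of the centered
  matrix), the dimensionality at threshold τ is
  `d_τ = min{ k : Σ_{i≤k} p_i ≥ τ }` — 1 for perfectly synchronous channels,
  up to `F` for fully decoupled ones.
* **Genetic-algorithm feature selection.** Individuals are feature subsets
  (≤ 15 of > 1,000 deterministic TOF/ATT features); fitness is
  `|r(PC1(subset), target)|`, the absolute Pearson correlation between the
  subset's first principal component and a clinical score (SOFA, ICDSC,
  lactate, PCT, creatinine, bilirubin).
* **Classification.** SVM on the GA components with stratified, patient-
  grouped fivefold cross-validation; accuracy / sensitivity / specificity,
  ROC and AUC; and a per-patient first-half/last-half classifier with
  correct / wrong / undecided verdicts.
* **Statistical report.** Median (0.25–0.75 quartile) group comparisons
  with Kruskal–Wallis followed by Mann–Whitney U, chi-squared for CAM-ICU
  rates, and absolute-Pearson correlation tables.
* **Synthetic cohorts.** 10 septic + 10 control patients with
  severity-linked clinical scores and a dispersive signal model whose
  channel desynchronisation grows with severity (see the methods
  vignette, `vignettes/acg-methods.Rmd`).

## Worked example

```r
library(acgtools)

cohort <- generate_cohort(cohort_config(), seed = 1)
cohort
#> ACG cohort: 20 patients (10 SG, 10 CG), 60 patient-days, 10 freq channels, seed 1

dims <- dimensionality_summary(cohort, threshold = 0.90)
head(dims, 4)
#>   patient_id day dim_tof dim_att dim_mean
#> 1        P01   1     6.5     7.0     6.75
#> 2        P01   3     6.6     6.5     6.55
#> 3        P01   7     5.7     5.8     5.75
#> 4        P01  14     4.0     4.1     4.05

features <- build_feature_table(cohort)   # 60 patient-days x 1010 features
std <- standardize_features(features)
ga <- ga_evolve(std, "sofa",
                ga_config(population_size = 300, generations = 60,
                          early_stop = TRUE, seed = 2))
ga
#> ACG GA result (target sofa): best fitness 0.9619 with 14 features after 60 generations
#>   features: tof_f05_acf1, tof_f06_acf1, ..., att_f02_f03_sdratio

labels <- label_positive(features$targets$sofa, features$targets$icdsc)
cv <- crossval_svm(cbind(sofa = pc1_scores(ga$best, std)), labels,
                   row_key = features$row_index, k = 5, seed = 3)
cv
#> ACG 5-fold CV: accuracy 84.71%, sensitivity 84.44%, specificity 87.50%
roc_curve(cv$scores, cv$labels)
#> ACG ROC curve: 62 points, AUC 0.9542
```

Patient P01 (septic) needs 6–7 principal components to explain 90% of its
channel variance at inclusion, falling as it recovers; controls sit near 1.
The GA finds a 14-feature subset — dominated by attenuation contrasts and
TOF autocorrelations — whose first principal component correlates at 0.96
with SOFA, and a linear SVM on that component screens positive patient-days
(ICDSC or SOFA ≥ 3) at ~85% cross-validated accuracy.

`run_pipeline(pipeline_config(seed = 1))` chains all stages
(simulate → features → dimensionality → GA → classify → report), writes one
artifact per stage (CSV/JSON) and resumes from existing artifacts.

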