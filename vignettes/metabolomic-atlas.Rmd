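---
title: "Methods: building and stress-testing a disease-wise metabolomic atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and stress-testing a disease-wise metabolomic atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaboatlas)
```

## The analysis model

`metaboatlas` treats a cross-sectional cohort as a table of participants ×
{metabolite features, clinical covariates, medication flags, region label,
phenotype codes}. Phenotypes live in a two-level class/subclass hierarchy;
each retained class and subclass is contrasted against one *shared* control
pool — all phenotype-free participants — rather than per-phenotype "rest of
cohort" controls. This matches the design of prevalent-disease biobank
analyses in which every condition is compared with the disease-free group,
and it makes profiles of different phenotypes directly comparable because
they share a standardization reference.

### Disease profiles

For phenotype $p$ with case set $C_p$ and control set $N$, each retained
feature $j$ is standardized by the control moments,
$z_{ij} = (x_{ij} - \mu_j^N)/\sigma_j^N$, and the profile is
$\mathrm{meanZ}_{pj} = \frac{1}{|C_p|}\sum_{i \in C_p} z_{ij}$. Referencing
controls (rather than the pooled sample) centers the null at zero: when
cases are exchangeable with controls, $\mathrm{meanZ} \to 0$. The *altered
set* is $A_p = \{ j : |\mathrm{meanZ}_{pj}| > \tau \}$ with $\tau = 0.5$
and a strict inequality — a feature sitting exactly at the threshold is
not altered. Values are median-imputed before standardization by default
(`impute = FALSE` switches to complete-case moments); which convention a
published analysis used is rarely stated, so both are exposed.

### Composite similarity and clustering

Inter-disease similarity blends set overlap and profile shape:

$$S = \omega J + (1-\omega) R', \qquad
  J = \frac{|A_a \cap A_b|}{|A_a \cup A_b|}, \qquad
  R' = \frac{\rho_{\mathrm{Spearman}} + 1}{2},$$

with $\omega = 0.5$. The two components are deliberately complementary:
$J$ sees only which features are materially altered (robust to rank noise
among null features), $R'$ sees the full profile ordering (robust to
threshold effects). The affine map $(\rho+1)/2$ is the unique monotone
linear rescale of $[-1,1]$ onto $[0,1]$. Degenerate cases are defined,
not left to chance: two *empty* altered sets are identical sets
($J = 1$, flagged), and a zero-variance profile is uninformative
($R' = 0.5$, flagged).

Clustering uses complete linkage on $D = 1 - S$ — the minimal monotone
conversion, keeping merge heights in $[0,1]$. The agglomerator is written
for determinism: ties in the minimal inter-cluster distance (tolerance
$10^{-12}$) are broken by the lexicographically smallest pair of cluster
labels (a cluster is labeled by its smallest leaf), and leaf order is the
recursive traversal with the smaller-labeled subtree first. Atlases are
therefore byte-identical across runs, platforms and phenotype input
orders. Partition cuts remove the $k-1$ highest merges; a tie at the cut
height is resolved by merge order and flagged. Partition agreement is the
permutation-model Adjusted Rand Index from the contingency table; the
degenerate denominator (both partitions trivial) returns 1 for identical
partitions and 0 otherwise.

### Statin robustness

Prevalent-disease cohorts are heavily medicated, and statins shift exactly
the lipid features that dominate cardiometabolic profiles. The package
probes this by per-feature least-squares residualization on the statin
indicator (optionally plus covariates), then rebuilding the atlas on the
standardized residuals and comparing partitions with an ARI sweep over
$k$. With only the indicator in the model, residual group means are
exactly balanced across flag levels — an OLS identity the tests assert at
$10^{-8}$. One caveat the package makes explicit: when medication
prevalence differs between cases and controls, the indicator is a proxy
for disease, and residualizing on it removes part of the disease signal
*even when the medication has no pharmacological effect*. The "inert
machinery" robustness check (adjusted = unadjusted at every $k$) is
therefore run under a flag that is independent of disease; the corrective
check (adjustment moves the partition closer to the planted truth) uses
differential prevalences with a strong negative lipid effect.

### Discrimination harness

Each phenotype is modeled against the shared controls with three
algorithms — ridge-penalized logistic regression (`glmnet`), random
forest (`ranger`), gradient boosting (`xgboost`) — on three feature sets
(metabolites / clinical / combined). Nested 5-fold cross-validation
separates tuning from estimation: inner folds select the hyperparameter
configuration with the best mean AUC, outer folds are scored by models
refit on the outer-training set. Every preprocessing statistic (median
for imputation, mean/SD for z-scoring, the zero-SD feature drop) is
computed on training rows only and applied unchanged to validation,
hold-out and explanation data; the tests corrupt held-out rows and assert
bit-identical fits as a leakage sentinel. The missingness filter
(exclude features with **more than** 20% missing; exactly 20% is kept) is
computed once on the full analysis cohort, since it defines the shared
feature universe rather than a fold-level statistic.

Class imbalance is handled by inverse-prevalence observation weights
($w = n / (2 n_{\text{class}})$) in all three algorithms — deterministic,
unlike resampling — which also makes the 0.5 probability threshold
meaningful for sensitivity/specificity/balanced accuracy. The headline
estimate is the pooled AUC over concatenated outer-fold scores (per-fold
AUCs are also reported); CIs are percentile bootstrap over participants,
resampled within class so both classes persist, B = 1,000. Geographic
hold-out participants never enter any fold; the final pipeline (modal
selected configuration, refit on all discovery data) is applied to them
unchanged. Every result carries events-per-variable
($\mathrm{EPV} = n_{\text{cases}} / n_{\text{features}}$) and a low-EPV
flag (default threshold 5, configurable; the overfitting concern is
qualitative, so no canonical value exists).

Default grids are small and exposed in `model_spec()`: ridge strength
$\lambda \in \{0.01, 0.1, 1, 10\}$; boosting 200 trees, depth
$\{3, 6\}$, learning rate $\{0.05, 0.1\}$; forest 300 trees, depth
$\{\text{unlimited}, 8\}$.

### Attributions and consensus

Per-feature attributions satisfy local accuracy: baseline plus the sum of
feature attributions equals the model margin for every sample. Linear
models use the exact closed form $\beta_j (x_j - \bar b_j)$; gradient
boosting uses the exact tree-path decomposition (the library evaluates it
in single precision, so agreement is $\sim 10^{-7}$ relative to margin
scale — the tests check $10^{-6}$ absolute at unit-scale margins and the
relative bound on larger models); random forests fall back to an
interventional permutation-sampling estimator whose residual is spread
equally over features to restore additivity exactly, flagged
`approximate`. Attribution direction is the sign of the Pearson
correlation between feature values and per-sample attributions.

Consensus selection counts, per feature, the phenotypes in whose top-$k$
ranking it appears ($k = 30$, descending mean $|$attribution$|$, ties
broken lexicographically and flagged), requires recurrence $\geq n_{\min}$
(default 10) and direction consistency $\geq c_{\min}$ (default 0.8), and
pools classes and subclasses (a level-restricted run is a filter away).
The consensus panel size is an outcome, never a parameter. Flow-diagram
edge tables are restricted to combined-model attributions; when several
algorithms are supplied the best performer per phenotype (pooled AUC) is
explained — both conventions configurable.

## The synthetic generator

`generator_config()` emulates the statistical structure the analysis
assumes, with defaults chosen once as desk-scale conventions:

* **Metabolites**: $x = e^{L}$ with $L$ multivariate normal — right-skewed
  marginals as NMR panels show. Baseline log-mean 1.0, log-SD
  $\sigma = 0.25$ (coefficient of variation ≈ 25%, typical of lipoprotein
  measures). Correlation is block-diagonal with constant within-block
  correlation 0.5 over 9 blocks, mirroring biomarker groups; the first
  ~4/9 of blocks are "lipid" blocks.
* **Planted structure**: classes cycle through three groups — *lipid*
  (a 20-feature shared signature inside the lipid blocks, shift 1.0
  control-SD on the log scale), *renal-like* (a separate 10-feature
  signature, same shift), and *null* (no planted shifts; emulating
  conditions without a systemic metabolic signature). Each non-null
  subclass additionally gets 5 private features at shift 0.8. Shifts are
  planted on the log scale so the raw-scale profile has a closed form:
  for log shift $d$, $\mathrm{meanZ} = (e^{d}-1)/\sqrt{e^{\sigma^2}-1}$,
  which the recovery tests use as their oracle (the small-$\sigma$
  approximation $\mathrm{meanZ} \approx d/\sigma$ is biased upward by
  the lognormal variance inflation and is not used).
* **Confounding**: a statin flag with prevalences 36.26% (cases) / 6.77%
  (controls) — the published medication split — additively shifts all
  lipid-block features by a signed log-scale effect (default −0.5 SD).
* **Nuisance structure**: MCAR missingness (default 5%), a small fraction
  of participants lacking the whole panel (2%) and carrying a generic
  exclusion flag (2%) to exercise the exclusion ledger, three region
  labels at 0.9/0.05/0.05, and 5 clinical covariates with a +0.5 SD case
  shift so combined models can beat metabolite-only ones.

What it does **not** emulate — and what passing tests therefore do not
establish about real data: assay batch effects and measurement drift,
informative missingness, multimorbidity (each synthetic case carries one
subclass code), realistic effect-size spectra (published studies do not
report them; the defaults are conventions), label noise, and covariate
confounding beyond the statin flag.

## Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to keep the full suite in
minutes on one CPU while leaving comfortable statistical margins:
atlas-recovery and statin-robustness cohorts use 5,200 participants,
60 metabolites, 20 clinical covariates and 9 phenotypes (3 classes × 2
subclasses, ~330 cases each); the null-model leakage check uses a
balanced 2,000-participant, 40-metabolite cohort with full default grids;
the consensus run uses a single boosting configuration (the inner loop is
then degenerate by construction) with $n_{\min} = 3$, covering the three
lipid-group phenotypes. Planted-shift recovery uses ~960 cases because
the lognormal case variance inflates the meanZ sampling SD by
$e^{d}$.

Other numerical conventions: participant ids are sorted before every
seeded shuffle; all seeds are explicit and every derived stream hashes a
(seed, label) pair; zero-SD features are dropped with a warning rather
than producing infinities; Mann–Whitney p-values use the tie-corrected
normal approximation without continuity correction (so identical samples
give exactly $p = 1$), and an all-tied comparison returns $p = 1$ with a
warning; BH correction is applied across all cells of one call, with the
family size recorded in the output.

## Known limitations

The atlas is descriptive: similarity of control-referenced profiles is
not evidence of shared etiology, and cross-sectional discrimination is
not prospective prediction. The statin residualization is linear and
single-medication; real polypharmacy needs richer treatment models. The
complete-linkage/`1 - S` choices are one point in a family of defensible
conventions — alternative linkages or rescalings can change local
topology, which is why the ARI machinery for comparing partitions is part
of the package rather than an afterthought.
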