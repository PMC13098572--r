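# metaboatlas

Tools for building a **disease-wise metabolomic atlas** from tabular
case–control cohorts with NMR-style metabolite panels.

Large biobank studies profile hundreds of circulating metabolites
(lipoprotein subfractions, fatty-acid compositions, amino acids,
inflammation markers) across participants carrying dozens of distinct
disease diagnoses. Two questions recur: *which metabolic alterations are
shared across many conditions, and which are condition-specific?* — and
*is the apparent organization of diseases in "metabolic space" robust to
confounding by medication (statins in particular)?* `metaboatlas`
implements a complete, testable pipeline for this kind of analysis, aimed
at biostatisticians and computational epidemiologists.

## What it computes

For each disease phenotype (organized in a class/subclass hierarchy) versus
a shared phenotype-free control pool:

1. **Disease profiles.** Each retained metabolite is standardized by the
   control mean and SD; the profile is the mean z-score over cases
   (`meanZ`). Metabolites with `|meanZ| > 0.5` form the phenotype's
   *altered set*. Group differences are tested by two-sided Mann–Whitney
   *U* with Benjamini–Hochberg FDR correction.
2. **Composite inter-disease similarity.** For phenotypes *a*, *b*:

   *S(a,b) = ω·J(a,b) + (1−ω)·R′(a,b)*,

   where *J* is the Jaccard overlap of altered sets, *R′ = (ρ+1)/2* is the
   Spearman correlation of `meanZ` profiles rescaled to [0, 1], and
   *ω = 0.5* by default. Phenotypes are clustered by deterministic
   complete-linkage on *D = 1 − S*; partitions at any cut level *k* are
   compared with the **Adjusted Rand Index** (ARI). Statin confounding is
   probed by re-running the atlas on per-metabolite residuals from a
   regression on the statin-use indicator.
3. **Discrimination models.** Nested 5-fold cross-validation (inner folds
   tune hyperparameters, outer folds estimate performance) of ridge
   logistic regression, random forest and gradient boosting on three
   feature sets (metabolites / clinical / combined), with leakage-safe
   fold-wise median imputation and z-scoring, stratified bootstrap AUC
   CIs (B = 1,000), geographic hold-out validation, and events-per-variable
   (EPV) overfitting flags.
4. **Cross-disease consensus features.** Shapley attributions (exact for
   linear and tree models) are ranked per phenotype; features recurring in
   the top-30 of at least `n_min` phenotypes with consistent direction form
   the consensus panel, which can be re-evaluated as a parsimonious model.

A **synthetic cohort generator** with planted effect structure
(block-correlated log-normal metabolites, a shared lipid signature, a
renal-like second signature, a null phenotype group, statin perturbation,
MCAR missingness, three region labels) makes every stage testable without
restricted data — ground truth ships with each generated cohort.

## Worked example

```r
library(metaboatlas)

cfg <- generator_config(n_participants = 3000, n_metabolites = 60,
                        n_clinical = 20, case_fraction_per_phenotype = 0.05,
                        statin_effect = 0, seed = 11)
cohort  <- generate_cohort(cfg)
ex      <- apply_exclusions(cohort)
ex$ledger
#> # A tibble: 3 × 3
#>   step                 n_removed n_remaining
#> 1 enrolled                     0        3000
#> 2 missing_metabolomics        56        2944
#> 3 exclusion_flag              62        2882

frame   <- build_phenotype_frame(ex$cohort, min_cases = 50)
atlas   <- build_atlas(ex$cohort, frame)          # profiles + S + dendrogram
round(atlas$S[1:3, 1:3], 2)
#>       C01  C02  C03
#> C01  1.00 0.16 0.35
#> C02  0.16 1.00 0.17
#> C03  0.35 0.17 1.00

part <- cut_partition(atlas, k = 3)
adjusted_rand_index(part, planted_partition(cohort, atlas$phenotypes))
#> [1] 1
```

The `S` entries are composite similarities in [0, 1]: here the two
subclasses of each planted disease group sit near their class (e.g.
`S(C01, C01.1) ≈ 0.9`) while unrelated groups stay near 0.2. The `k = 3`
cut recovers the three planted phenotype groups exactly (ARI = 1).
`autoplot(atlas)` draws the similarity heatmap in dendrogram leaf order;
`atlas_newick(atlas)` exports the dendrogram; `run_pipeline(run_config(...),
out_dir)` runs every stage end-to-end with a reproducibility manifest.

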