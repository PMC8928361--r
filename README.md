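# alffradiomics

Region-wise **multi-order radiomics classification of ALFF brain maps**,
for neuroimaging researchers who want a tested, reproducible
implementation of the now-standard "texture-features + nested-CV
LASSO/SVM" workflow for separating Parkinson's disease (PD) patients
from healthy controls (HC) — and for anyone who needs its building
blocks (3D gray-level co-occurrence/run-length features, stationary
wavelet subbands, leakage-free nested cross-validation, permutation
significance, discriminative-region reports).

## What it computes

Given per-subject 3D ALFF maps and an integer parcellation atlas on a
common grid:

* **432 features per region**: 15 first-order histogram statistics + 33
  texture features (22 GLCM + 11 GLRLM, 13 directions, distance 1) on
  the original map, and the same 48 on each of 8 stationary coiflet-1
  wavelet subbands (LLL…HHH): 48 × 9 = 432.
* **Classification**: per-set z-scoring; inside every training fold a
  two-sample t-test filter (*p* < 0.05) then LASSO logistic selection
  over λ ∈ (0.05, 0.10, …, 0.60); linear SVM (C = 1). Performance by
  nested stratified cross-validation (10×10, 20 repeats at full scale)
  with accuracy, sensitivity, specificity, precision, recall, F1,
  balanced accuracy = (sens + spec)/2, and rank-based AUC.
* **Significance**: label-permutation test rerunning the whole pipeline
  per shuffle; *p* = (1 + N<sub>GP</sub>)/(1 + N).
* **Interpretation**: region selection frequencies across folds, top-10
  discriminative regions with mean SVM weights, and Spearman
  correlations with clinical scores (HDRS-17, UPDRS, MMSE, …) in PD
  subjects.
* **Synthetic cohorts**: `make_atlas()` + `simulate_cohort()` generate
  smooth ALFF-like maps with injected group effects and copula-linked
  clinical scores, so everything runs with no data download.

## Worked example

```r
library(alffradiomics)

atlas <- make_atlas(c(24, 24, 24), n_regions = 30, seed = 1)
eff   <- list(effect_spec(5, mean_shift = 0.4),
              effect_spec(15, mean_shift = 0.4),
              effect_spec(25, mean_shift = 0.4))
coh   <- simulate_cohort(atlas, cohort_spec(n_pd = 30, n_hc = 30,
                                            effects = eff, seed = 2))
ft    <- build_feature_table(coh$volumes, atlas, coh$subjects)
z     <- zscore_fit_apply(ft)$table
fit   <- nested_cv(z, coh$subjects$group, desk_config(base_seed = 11))
fit
#> <nested_cv> 5-fold x 5 repeats on 60 subjects
#>   mean accuracy 0.9600  AUC 0.9920  sensitivity 1.0000  specificity 0.9200
#>   modal lambda 0.50
```

The mean accuracy (0.96) and AUC (0.99) say the two simulated groups —
which differ by a mean ALFF shift of twice the background voxel SD in 3
of 30 regions — are almost perfectly separable by the selected features;
the modal λ (0.50) is the penalty most outer folds preferred.
Continuing,

```r
final <- finalize_model(z, coh$subjects$group, fit$fold_records)
top_regions(fit$fold_records, k = 10)$top_regions |> head(3)
#>   region frequency
#> 1     25      0.56
#> 2      5      0.24
#> 3     15      0.20
```

the three injected regions head the discriminative ranking — the
recovery the report stage is for. (On near-separable data like this the
L1 penalty keeps only one representative feature per fold, so the
frequencies split across the correlated injected regions; see the
methods vignette.) A one-call
replica of the whole workflow (simulate → extract → train → validate →
permute → report, with a manifest of seeds and output hashes) is

```r
run_all("results/demo", config = desk_config(base_seed = 1))
```

A thin CLI with the same stages as subcommands is installed at
`inst/cli/alffradiomics`.

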