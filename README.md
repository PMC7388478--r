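# brcaradiomics

Lasso-principal-component regression (L-PCR) for predicting germline
**BRCA1/2 carrier status** from breast-MRI lesion texture, for radiologists,
genetic-counselling researchers and statisticians studying imaging-based
pre-selection for genetic testing.

Affected high-risk breast-cancer patients are routinely triaged for BRCA1/2
sequencing by subjective criteria (family cancer history, receptor status).
This package implements, as a reusable and fully tested pipeline, an
alternative signal source: computer-extracted texture of the contrast-enhanced
lesion in subtraction MRI, combined with the standard clinical covariates.
Because the clinical image data such studies rest on are not redistributable,
the package also ships a synthetic phantom-cohort generator so that the entire
pipeline is exercisable and testable offline.

## The model

For subject $i$ with feature vector $x_i$ (imaging principal-component scores
and/or clinical covariates) and carrier status $y_i \in \{0,1\}$, the
estimator is the penalized logistic regression

$$\min_{\beta_0,\beta}\; \frac{1}{n}\sum_{i=1}^n
  \Big[\log\big(1+e^{\beta_0+x_i^\top\beta}\big) - y_i(\beta_0+x_i^\top\beta)\Big]
  \;+\; \lambda\Big[\alpha\lVert\beta\rVert_1
  + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\Big],$$

with predictors standardized internally and $\alpha = 1$ (lasso) by default.
The imaging features are built as follows:

1. **Patch extraction** — seed points are drawn uniformly inside the manually
   segmented lesion mask (~1000 per image, cohort-level 1:1 carrier:control
   patch ratio) and a 65×65 in-plane intensity window (4225 voxels) is cut
   around each seed and min–max normalized to [0, 1].
2. **PCA** — the patch features are reduced by principal component analysis,
   keeping the smallest number of components explaining ≥ 95 % of variance.
3. **Tuning** — $\lambda$ is selected on the grid 0–3 (step 0.05, 61 points)
   by repeated stratified 5-fold cross-validation (L = 20 repeats),
   maximizing the mean held-out AUC (the Mann–Whitney probability that a
   random carrier is ranked above a random control). Designs with ≤ 2
   predictors use plain maximum-likelihood logistic regression instead.

Cohort-level statistics from the same study design are included: exact
two-sided binomial tests (minimum-likelihood convention), Welch t-test from
group summaries, Spearman correlation matrices, and empirical-probability
(EP) assignment from family structure.

## Worked example

```r
library(brcaradiomics)

cfg    <- synthetic_cohort_config(rng_seed = 42)   # 16 carriers, 25 controls
cohort <- generate_cohort(cfg)
ps     <- build_cohort_patches(cohort$subjects,
                               sampling_plan(n_per_image = 100, rng_seed = 1))
ps
#> <patch_set> 5600 patches of 65x65 (4225 features); 2800 positive / 2800 negative

pcs <- imaging_pc_scores(ps, tau = 0.95, mode = "mean")
pcs$model
#> <pca_model> 40 components; retained 13 at tau = 0.95 (cum. EVR 0.9533)

cv <- cross_validate(pcs$scores$X, pcs$scores$labels, k = 5, L = 20, rng_seed = 1)
cv
#> <cv_curve> 61 lambda points, k = 5, L = 20; optimal lambda = 0.4 (mean CV AUC 1)

sp  <- experiment_spec("imaging_tnbc", c("imaging", "tnbc"))
res <- run_experiment(assemble_design(cohort$covariates, pcs$scores, sp),
                      sp, rng_seed = 1)
res
#> <experiment_result> 'imaging_tnbc' (penalized): mean CV AUC 1 at lambda = 0.4; selected: PC1

exact_binomial_two_sided(13, 16, 0.66)
#> Exact two-sided binomial test: k = 13, n = 16, null p = 0.66; p-value = 0.2916
```

The patch set is balanced (2800/2800) even though the cohort is not (16/25);
13 principal components carry 95 % of the patch variance at this reduced
sampling density; and the cross-validated AUC of 1.0 reflects the default
generator's deliberately strong planted texture contrast — real lesions are
far noisier (see the vignette). The binomial p-value 0.292 is the carrier
BRCA1-fraction comparison against its literature prevalence (13/16 observed
vs 66 %): no evidence of cohort bias.

A command-line interface wraps the same stages:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "brcaradiomics", package = "brcaradiomics"))')
Rscript "$CLI" simulate --out cohort_dir --seed 7
Rscript "$CLI" run --cohort cohort_dir --out results_dir --seed 7
Rscript "$CLI" stats --table cohort_dir/covariates.tsv --out stats_dir \
        --binomial "13,16,0.66"
```

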