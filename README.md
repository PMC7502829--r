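# faburden

Individual-level **lesion-load analysis of skeletonized fractional
anisotropy (FA)** with a prognostic machine-learning layer, for studies
of mild traumatic brain injury (mTBI) where white-matter injury is
spatially heterogeneous and acute FA can be abnormally *high* or
abnormally *low* in different tracts.

The package is aimed at neuroimaging researchers who have TBSS-style
skeletonized FA maps in a common space (one scalar NIfTI volume per
subject, a binary skeleton mask, an integer tract atlas) plus subject
tables (age/sex/education covariates, serum cytokines, cognitive scores
at baseline and follow-up), and who want to ask: *do acute diffusion
abnormalities predict which patients fail to recover normal information
processing speed months later?*

## What it computes

1. **Normative EZ mapping** — controls are split into covariate-matched
   *reference* and *normal* halves; per-voxel OLS of FA on (age, sex,
   education) adjusts FA where effects are significant (p < .05); a
   bootstrap over reference subjects stabilizes the per-voxel normative
   mean μ(v) and SD σ(v); each subject's deviation map is

       EZ(v) = (FA_adj(v) − μ(v)) / σ(v),   abnormal iff |EZ| > 1.96.

2. **Bidirectional cluster detection** — suprathreshold voxels are
   masked by tract atlas and skeleton; connected components (26-
   connectivity, per tract) must exceed an extent threshold k controlling
   the family-wise error at α = .05, from either 3D Gaussian-random-field
   theory or a Monte-Carlo null simulated on the actual skeleton mask
   (the default there — the skeleton is quasi-2D). Thresholds can also be
   chosen by an ROC sweep maximizing patient/control separation of total
   lesion load.

3. **Lesion-load features** — a fixed group catalogue of high/low
   clusters (voxels abnormal in ≥ 25% of patients, extent ≥ k); the mean
   covariate-adjusted FA per cluster per subject is the feature.

4. **Prognosis** — linear SVM with recursive feature elimination
   (SVM-RFE, max-normalized weights), leave-one-subject-out CV, repeated
   subsampling CIs, label-permutation p-values, ε-SVR prediction of
   continuous processing-speed and working-memory scores (Spearman ρ),
   serum-cytokine domain combination, frozen external validation on a
   replicate cohort, and a top-25%-weight + Bonferroni importance filter.

A **synthetic-cohort generator** (`simulation_config()`,
`generate_cohort()`) reproduces the statistical structure the analysis
assumes — smooth Gaussian FA noise with known FWHM, covariate effects,
graded bidirectional lesions in named tracts, cytokine elevations, and
follow-up scores driven by lesion burden — so the entire pipeline is
testable without any clinical data. No real data ship with the package.

## Worked example

```r
library(faburden)

cfg    <- simulation_config(seed = 1)        # 40 controls + 60 patients
bundle <- generate_cohort(cfg)

ctl <- bundle$covariates$id[bundle$covariates$group == "control"]
pat <- bundle$covariates$id[bundle$covariates$group == "patient"]

model <- build_normative_model(bundle$fa[ctl, ], bundle$covariates,
                               B = 200, seed = 3)
ez    <- compute_ez(bundle$fa[pat, ], model, bundle$covariates)

k   <- mc_extent_threshold(1.96, 6, bundle$space, alpha = 0.05,
                           n_fields = 400, seed = 7)
cat_ <- build_cluster_catalogue(ez, 1.96, as.integer(k), bundle$space,
                                bundle$atlas, frequency_fraction = 0.25)
print(cat_)

X <- extract_features(adjust_fa(bundle$fa[pat, ], model,
                                bundle$covariates), cat_)
y <- label_recovery(bundle$outcomes[bundle$outcomes$id %in% pat, ],
                    cfg$norms_table)[pat]

rfe <- rfe_select(X, y)
print(loocv_classify(X, y, rfe$optimal))
```

Output (R 4.3, seed exactly as above):

```
<cluster_catalogue> 4 cluster(s) in 4 tract(s) (u=1.96, k=40, pooling >= 25%)
<model_report> accuracy 96.7%, sensitivity 90.9%, specificity 100.0% (positive class: -1 = not recovered)
```

The catalogue recovers the four injected lesions (two low-FA, two
high-FA, one per configured tract) above the 40-voxel extent threshold
that a smooth Gaussian null field on this skeleton would exceed with 5%
family-wise probability. The LOOCV report says that the mean cluster FA
values measured in the acute maps identify the patients whose follow-up
Trail-Making-Test-A time stays above their age- and education-adjusted
cut-off ("not recovered", coded −1 and treated as the clinically
positive class) with 96.7% accuracy — 90.9% of non-recovering patients
are caught, with no false alarms among the recovered.

## The full analysis

`analysis/` contains the numbered drivers of the complete study —
simulate original + replicate cohorts, fit the normative model, build
the catalogue, train/validate the prognostic models, externally validate
the frozen model — each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_normative_ez.R
Rscript analysis/03_cluster_catalogue.R
Rscript analysis/04_prognostic_models.R
Rscript analysis/05_external_validation.R
```

The methods vignette (`vignettes/lesion-load-prognosis.Rmd`) documents
the model, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, and the numerical
choices.

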