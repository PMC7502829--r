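---
title: "Lesion-load analysis of skeletonized FA and prognosis of processing-speed outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-load analysis of skeletonized FA and prognosis of processing-speed outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mild traumatic brain injury (mTBI) usually leaves no trace on CT or
conventional MRI, yet roughly a third of patients develop persistent
deficits of information processing speed (IPS). Diffusion-tensor imaging
detects the underlying white-matter injury, but the injuries are
*spatially heterogeneous*: different patients damage different tracts,
and acute fractional anisotropy (FA) can be abnormally **high** (axonal
swelling, astrogliosis) or abnormally **low** (fiber disruption).
Group-level voxelwise statistics, which assume overlapping lesions,
therefore wash the signal out.

`faburden` implements an individual-level *lesion-load* strategy
instead: each patient's skeletonized FA map is converted into a z-map of
deviation from a healthy-reference norm, abnormal voxels are aggregated
into tract-wise clusters of either direction, and the per-cluster mean FA
values become predictor features for prognostic models of long-term
cognitive outcome. Because no clinical data ship with the package, a
synthetic-cohort generator reproduces the statistical structure the
analysis assumes, and every stage is tested end-to-end against that
generator's ground truth.

## The normative EZ model

Controls are split into two covariate-matched halves: a *reference
group* that defines the norm and *normal controls* held out for
calibration and threshold optimization. The split is greedy pairwise
matching on standardized (age, sex, education): the closest pair is
assigned one subject per half, oriented to shrink the running covariate
imbalance.

At every skeleton voxel $v$, FA is regressed on age, sex and education
in the reference group (OLS, covariates centred at reference means). The
omnibus F-test at uncorrected $p < .05$ defines the voxels at which
covariate adjustment is applied — the adjustment subtracts
$\sum_j \hat\beta_j(v)\,(x_j - \bar x_j^{\mathrm{ref}})$ there, and
leaves all other voxels untouched. No multiple-testing correction is
applied to this mask by design: the mask gates a covariate *adjustment*,
not an inference, and a conservative mask would leave age effects in the
deviation maps.

A nonparametric bootstrap stabilizes the norm against reference
sampling: for $b = 1,\dots,B$ (default $B = 1000$), the reference
subjects are resampled with replacement, the covariate model is refit on
the resample, and the per-voxel mean and SD of the **full unique
reference group adjusted with that replicate's coefficients** are
accumulated; $\mu(v), \sigma(v)$ are the averages over replicates.

Accumulating over the unique subjects rather than the resample is a
deliberate deviation from the more obvious "mean/SD of the resample":
with the covariate refit inside the replicate, duplicated subjects carry
duplicated error terms that the refit can chase, deflating the SD by
roughly 17% at $n_{\mathrm{ref}} = 20$ and inflating the null
$|EZ| > 1.96$ rate to ~12%. The implemented form keeps the bootstrap's
propagation of reference sampling variation (through the coefficients)
without that artifact.

Three finite-sample calibrations are applied by default
(`sd_correction = TRUE`):

* residual degrees of freedom $n - 4$ in the replicate SD at
  covariate-adjusted voxels (three slopes plus the mean);
* the $c_4$ unbiasing constant for the SD;
* a $\sqrt{1 + 1/n_{\mathrm{ref}}}$ prediction factor in the EZ
  denominator, because a scored subject is *outside* the reference
  sample.

Without them, plain z-scoring against a 30-subject reference flags
~6.4% of null voxels at $|EZ| > 1.96$ (t-distribution arithmetic) rather
than the nominal 5%; with them the measured null rate is within
$5\% \pm 1$ pp. `sd_correction = FALSE` (with `identity_boot = TRUE`,
$B = 1$) reproduces the plain sample mean/SD exactly, which is the
degenerate configuration the unit tests use to pin the plumbing.

The deviation map is
$EZ(v) = (FA_{\mathrm{adj}}(v) - \mu(v)) / \sigma(v)$, thresholded
strictly: $|EZ| > 1.96$, boundary excluded.

## Cluster detection and the extent threshold

Suprathreshold voxels are masked by the tract atlas and by the skeleton,
and connected components are computed **within each tract separately**
under 26-connectivity — skeletons are one to few voxels thick, and
face-only adjacency fragments genuinely contiguous tract segments.

Cluster extent is controlled at family-wise $\alpha = .05$ per
direction. Two nulls are provided:

* `grf_extent_threshold()` — the standard 3D Gaussian-random-field
  approximation, $E[m] = S\,(4\log 2)^{3/2} (2\pi)^{-2} (u^2 - 1)
  e^{-u^2/2} / f^3$ expected clusters and an exponential tail
  $P(n \ge k) = e^{-\beta k^{2/3}}$ matched to the expected cluster
  size, solved for the smallest $k$ with
  $1 - \exp(-E[m]\,P(n \ge k)) \le \alpha$;
* `mc_extent_threshold()` — a Monte-Carlo null that simulates smooth
  Gaussian fields (white noise convolved at the estimated FWHM on a
  padded grid, variance-normalized analytically) **on the actual
  skeleton mask** and takes the $1-\alpha$ quantile of the maximum
  cluster extent.

The analytic form matches the Monte-Carlo null within ~16% on full 3D
grids (the acceptance suite checks ±25% at $u = 1.96$, FWHM 3 voxels,
10,000 voxels). On the quasi-2D skeleton itself, however, 3D GRF
overcorrects by roughly a factor 3 (clusters cannot grow in the third
dimension), so the **Monte-Carlo mode is the default** for skeleton
analyses and GRF is kept as the fast analytic alternative.

Field smoothness is estimated from held-out-control residual maps: per
axis, the lag-1 autocorrelation $\rho$ of per-voxel-standardized
residuals gives $\mathrm{FWHM} = \sqrt{-2\log 2 / \log\rho}$ voxels,
clipped below at one voxel (white noise estimates at the clip).

The voxel threshold $u$ and extent threshold $k$ can be fixed
($u = 1.96$, $\alpha = .05$, the shipped default) or chosen by the ROC
sweep `optimize_thresholds()`, which maximizes the AUC of
patient-vs-held-out-control separation of total abnormal-voxel counts
over a $u \times \alpha$ grid (ties toward the stricter threshold).

## The group catalogue and features

The prognostic features must be a *fixed* set shared by all subjects.
How the published analysis pooled per-subject clusters into its fixed
53-cluster catalogue is not stated in the source; this package makes the
rule explicit: per direction, a voxel enters the group abnormality mask
when it is suprathreshold in at least `frequency_fraction` (default
0.25) of patients, and cluster detection is re-run on that mask. High
and low catalogues are independent, so a tract may contribute clusters
of both directions. Feature $(s, c)$ is the mean **covariate-adjusted**
FA of subject $s$ over cluster $c$ — adjusted rather than raw for
consistency with the EZ pipeline (the source is ambiguous; the choice is
logged in the catalogue provenance).

## Prognostic models

All classifiers and regressors are linear-kernel support-vector machines
(libsvm via `e1071`, $C = 1$, SVR $\varepsilon = 0.1$; the source names
the library but no hyperparameters). Features are z-standardized per
training fold — weight-vector ranking is scale-dependent.

* **SVM-RFE** (`rfe_select`): fit, drop the feature with the smallest
  $|w|$, repeat to one feature; the retained subset maximizes inner
  LOOCV accuracy (ties toward fewer features); weights are
  max-normalized so the top feature has weight 1.
* **LOOCV** (`loocv_classify`): standardization (and optionally the
  entire RFE, `refit_rfe = TRUE`) sits inside each fold. Sensitivity is
  anchored to the $-1$ (not-recovered) class — the clinically positive
  finding; the source never states its positive class, so every report
  records the convention.
* **Repeated subsampling** (`repeated_subsampling`,
  `subsampling_profile`): hold out $n = 1..8$ random subjects per
  repetition; the 2.5/97.5 percentiles of the repetition distribution
  are the reported CI (how the source computed its very tight CIs is
  unstated; this choice is documented in every report).
* **Permutation test** (`permutation_test`): labels reshuffled
  (class counts preserved), $p = (1 + \#\{acc_{\pi} \ge acc\}) /
  (1 + n_{\mathrm{perm}})$. `"full"` mode refits the entire RFE per
  permutation, so selection optimism cancels between observed and null
  — this is the calibrated mode and the one the type-I-error tests use.
  `"fast"` mode keeps the observed subset fixed; it is cheaper and
  slightly anticonservative, and reports label the mode. Whether the
  source refit its selection per permutation is unstated; both are
  provided.
* **SVR** (`svr_predict`): LOOCV prediction of the continuous score;
  Spearman's $\rho$ with a subject-bootstrap percentile CI. The working
  memory score reuses the IPS-trained feature subset without
  re-selection.
* **Domain combination** (`combine_domains`): imaging and cytokine
  blocks standardized separately, then concatenated.
* **External validation** (`finalize_model` + `external_validate`):
  the replicate cohort's features are cut with the *original* cohort's
  normative model and catalogue; the frozen model is applied once, no
  refitting, bit-identical reports for identical inputs.
* **Importance filter** (`importance_filter`): keep the top
  $\lfloor 0.25\,m \rfloor$ features by normalized weight, then require
  both group contrasts (not-recovered vs recovered, not-recovered vs
  controls) at Bonferroni $p < 0.05/m_{\mathrm{top}}$, with the
  normality-gated two-sample test of `group_stats()` (Shapiro–Wilk at
  .05 per group choosing a pooled-variance t-test or a rank-sum test;
  Cohen's d from the pooled SD).

Class imbalance (~1/3 positive) is left unreweighted, matching the
source's silence.

## The synthetic cohort generator

`simulation_config()` / `generate_cohort()` emulate, on a 48×48×24 grid
of 2 mm voxels, a 12-tract skeleton covering ~10% of the grid (parallel
slabs — contiguity and tract masking behave like a real skeleton;
curvature does not matter to any tested property):

* **Controls**: FA = smooth baseline (~0.5) + linear covariate effects
  (age −8·10⁻⁴/yr, sex +0.01, education +5·10⁻⁴/yr — small, realistic
  magnitudes) + Gaussian noise of marginal SD 0.04 smoothed at 6 mm
  FWHM (separable convolution, analytically rescaled to keep the
  marginal SD — GRF inference assumes smooth fields with known FWHM).
* **Patients**: four lesions (two abnormally low, two abnormally high
  FA) of 90 contiguous voxels at 3.5–4 reference-SD effect. Lesion
  sites are grown once from a dedicated `site_seed` that is *decoupled
  from the cohort seed* and constant by default: the strategic lesion
  locations belong to the injury model, so independently drawn original
  and replicate cohorts damage the same sites while every subject-level
  quantity varies — the premise under which a frozen model can be
  expected to transfer to a replicate cohort at all. Injury is *graded*: a fixed-count stratum of
  `round(0.33 · n)` patients draws severity U(0.8, 1.3) and the rest
  U(0, 0.35), with independent per-lesion jitter U(0.9, 1.1). An
  all-or-none stratum was rejected at design time: with binary burden,
  score prediction can only order the two groups, and Spearman's ρ is
  algebraically capped at 0.667 for a 1/3 prevalence — graded injury is
  also what the lesion-load premise describes.
* **Outcomes**: follow-up TMT-A = 27 + 0.027 · burden + N(0, 5) seconds
  (burden in effect-SD × voxels), BDS declining correspondingly;
  recovery labelled by comparing follow-up TMT-A against an (age ×
  education)-banded cut-off table. The published norms are cited but not
  printed in any shipped source, so a synthetic table with the expected
  structure ships as an editable CSV (`tmta_norms_synthetic.csv`); the
  cut-off is inclusive (≤ keeps the boundary recovered) — arbitrary but
  fixed.
* **Cytokines**: IL-1β, IL-6, CCL2 with control means/SDs and patient
  elevations matching the magnitudes the study reports (+0.4, +0.4,
  +47 pg/mL), scaled with injury grade (dose-response), so the cytokine
  domain carries weak real signal (~55–70% accuracy alone) and the
  combined model is at least as good as either single domain.

What the generator does **not** emulate: registration/projection error,
skewed and heteroskedastic clinical score distributions, site effects,
lesion-shape irregularity, and correlated multi-analyte panels. Passing
tests therefore demonstrate that the pipeline recovers the structure it
assumes — not that real cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* Strict `>` at every EZ threshold; ties in RFE weights drop the first
  (stable order); RFE accuracy ties prefer fewer features; ROC ties
  prefer larger $u$, then larger $k$.
* $\sigma(v) = 0$ anywhere is a hard error (degenerate simulation), not
  a floored value.
* Rank-deficient bootstrap replicates are redrawn and counted; more
  than 50% redraws aborts.
* An empty catalogue warns and the pipeline continues with cytokine
  features only.
* Permutation p-values use add-one smoothing (never exactly zero).
* The top-25% count uses `floor()` (27 features → 6).
* One master seed fans out to fixed per-stage offsets; every stochastic
  stage is reproducible in isolation and all seeds stay below $2^{31}$.

## Problem sizes used in the shipped analyses and tests

The default study is 40 controls + 60 patients (original) and 30 + 38
(replicate) on the 48×48×24 grid (~5,500 skeleton voxels); the
analysis scripts use $B = 1000$ bootstrap replicates, 1,000 Monte-Carlo
null fields, 5,000 permutations and 200 subsampling repetitions per test
size. The test suite exercises identical code at reduced sizes chosen
for minutes-scale runs (null calibration on a 64×64×32 grid with
~12,000 skeleton voxels and reference n = 30; $B$ = 40–200; 300–5,000
null fields; 49–500 permutations; 10–20 simulation seeds per property),
sizes at which every tested property has comfortable statistical margin.

## Known limitations

* The 3D GRF mode is only approximate on thin skeletons; it is
  validated against the Monte-Carlo oracle on full grids and shipped as
  the fast alternative, with Monte-Carlo as the skeleton default.
* LOOCV accuracy on null data is slightly pessimistic and
  majority-class-biased under imbalance; the no-leakage checks use the
  band the validation literature expects for ~60-subject cohorts.
* The probabilistic thalamo-cortical tract masks of the source are
  accepted as pre-made atlas labels; tractography is out of scope.
* With near-separable synthetic features, RFE's fewer-features
  tie-break legitimately collapses the subset to one or two clusters;
  the catalogue, not the subset, is the analogue of the published
  53-feature set.
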