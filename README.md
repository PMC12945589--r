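# strainmap

Normative brain shear-strain vulnerability mapping, and strain-stratified
analysis of diffusion-MRI tissue integrity in mild traumatic brain injury
(mTBI).

## The scientific problem

A long-standing biomechanical hypothesis holds that shear strain is the
principal mechanical cause of tissue damage in concussion: the brain regions
that concentrate the most shear strain under head loading should be the
regions that show the most injury. Magnetic resonance elastography (MRE)
measures how gentle, harmonic skull vibration deforms brain tissue in vivo,
yielding voxelwise strain tensors and complex shear moduli in healthy
subjects. Diffusion MRI in mTBI patients provides an independent, voxelwise
index of tissue integrity. `strainmap` implements the full analysis chain
that connects the two:

1. **Mechanical summaries** (`compute_oss()`, `compute_mps()`,
   `damping_ratio()`): from each subject's strain tensor field, the
   octahedral shear strain

   γ_oct = (2/3) √[(ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²]

   with ε₁ ≥ ε₂ ≥ ε₃ the tensor eigenvalues — a rotation-invariant summary
   of shear that ignores the volumetric strain component — plus the maximum
   principal strain ε₁ and the damping ratio ξ = G″/(2G′) from the complex
   shear modulus G* = G′ + iG″.

2. **Normative vulnerability map** (`zscore_within_subject()`,
   `normative_mean_map()`, `voxelwise_one_sample_t()`, `define_hs_mask()`):
   OSS maps are z-scored within subject across all brain voxels, averaged
   across the healthy cohort, and tested voxelwise (one-sample t against 0,
   Benjamini–Hochberg FDR over in-mask voxels). The **high-strain (HS)
   region** is the set of voxels with q < 0.05 *and* t ≥ 4; the low-strain
   (LS) region is its complement within the brain mask. Generalizability is
   checked by leave-one-out cross-validation (`loo_cross_validation()`):
   masks are rebuilt on n−1 subjects and the held-out subject's HS/LS strain
   is compared by a Wilcoxon matched-pairs signed-rank test.

3. **Apparent fiber density** (`fit_tensor()`, `estimate_response()`,
   `fit_csd()`, `afd_total()`): from single-shell diffusion MRI
   (b = 1000 s/mm², ~64 directions), a diffusion-tensor fit supplies FA, a
   single-fiber response function is calibrated from high-FA voxels, and
   constrained spherical deconvolution recovers the fiber orientation
   distribution (fODF). **AFDtotal** is the l = 0 spherical-harmonic
   coefficient of the fODF — an orientation-independent amplitude of
   diffusion-hindering tissue that is informative in gray and white matter
   alike.

4. **Strain-stratified statistics** (`build_bins()`, `subject_bin_means()`,
   `fit_lme()`, `delta_afd_curve()`, `mixed_anova_2x2()`, `ratio_ttest()`):
   the normative OSS z-map is discretized into 0.25-z bins; each subject's
   mean AFD per bin makes the subject (not the voxel) the unit of analysis.
   The central model is the random-intercept linear mixed model

   AFD_mean ~ group × OSS_bin_center + (1 | subject)

   whose group×OSS interaction asks whether AFD declines with normative
   strain *differentially* in mTBI versus controls. ROI-level tests (2×2
   mixed-design ANOVA; directed Welch t on the per-subject AFD_HS/AFD_LS
   ratio; sex-stratified variants) probe the pre-defined HS mask directly.

Because the package is exercised end-to-end on synthetic cohorts, a
first-class generator (`make_normative_field()`, `simulate_mre_cohort()`,
`simulate_afd_cohort()`, `simulate_dwi()`) plants known ground truth —
vulnerable high-strain blobs, modulus contrasts, group-specific AFD–strain
slopes, multi-compartment DWI signals — so that every stage can be verified
against what was planted.

## Worked example

```r
library(strainmap)

grid <- voxel_grid(c(32, 36, 32), voxel_size = c(2, 2, 2))
spec <- make_normative_field(grid, seed = 1)

# healthy MRE cohort -> normative statistics -> HS/LS partition
mre   <- simulate_mre_cohort(spec, n_subjects = 20, seed = 2)
zmaps <- lapply(mre$subjects, function(s) zscore_within_subject(s$oss))
stats <- voxelwise_one_sample_t(zmaps)
roi   <- define_hs_mask(stats, spec$mask, q_thr = 0.05, t_thr = 4)
roi
#> <strain_roi_mask> HS 478 voxels (3.7% of brain), LS 12314 voxels
#>   one-sample t (n=20, two-sided p) + BH FDR; joint rule q<0.05 & t>=4

# mTBI vs control AFD cohort, binned by normative strain, mixed model
cohort <- simulate_afd_cohort(spec, preset = "subacute_chronic",
                              n_control = 31, n_mtbi = 31, seed = 3)
fit <- fit_lme(bin_afd_cohort(cohort))
fit
#> <lme_result> AFD ~ group * OSS + (1 | subject), REML
#>   control slope     0.0404 [0.0399, 0.0409]
#>   mTBI slope        0.0288 [0.0283, 0.0293]
#>   interaction (c-m) 0.0116 [0.0109, 0.0123], p = 4.49e-152
```

The fitted slopes recover the generative preset (control 0.041, mTBI 0.029
AFD units per OSS z-score): AFD rises with normative strain in both groups
but less steeply in mTBI, so the positive interaction (control minus mTBI
slope) quantifies strain-dependent tissue loss. ROI-level tests on the same
cohort:

```r
rois <- roi_afd_summary(cohort, roi)
mixed_anova_2x2(rois)
#>   effect         df1   df2        F        p
#> 1 group            1    60     1.86 1.78e- 1
#> 2 region           1    60 50948.   1.34e-89
#> 3 group:region     1    60  1460.   8.14e-44
ratio_ttest(rois)
#> <ratio_test> t = 13.412 (df = 59.7), one-sided p = 5.69e-20 (mtbi_lower)

loo_cross_validation(zmaps)
#> <loo_result> 20 folds (0 excluded); HS > LS in 20/20; Wilcoxon V = 210, p = 1.91e-06
```

The significant group×region interaction and the directed ratio test say the
AFD deficit is concentrated in the high-strain region; the leave-one-out run
shows every held-out subject concentrates strain in the normatively defined
HS voxels. `autoplot()` methods draw the ΔAFD curve, ratio strip plots and
LOO fold plots; `run_pipeline(pipeline_config(...), output_dir)` chains all
stages and writes NIfTI/TSV/JSON outputs with provenance records.

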