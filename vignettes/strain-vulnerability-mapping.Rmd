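---
title: "Methods: normative strain vulnerability mapping and strain-stratified AFD analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative strain vulnerability mapping and strain-stratified AFD analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmap)
```

This vignette documents the models, the tunable parameters, the synthetic
data generator, and the numerical and design choices behind `strainmap`. It
is the package's account of *why* each stage is built the way it is; the
test suite and `scripts/acceptance.R` carry the corresponding empirical
checks.

## 1. Mechanical summaries

A voxel's strain state is a symmetric 3×3 tensor ε, stored as six components
in lower-triangular order (xx, xy, yy, xz, yz, zz). Two scalar summaries are
used:

* **Octahedral shear strain (OSS)**,
  γ_oct = (2/3)·√[(ε₁−ε₂)² + (ε₂−ε₃)² + (ε₃−ε₁)²], isolates the shear
  component: it is invariant to rotations and to adding any multiple of the
  identity (pure volumetric strain). The implementation uses the equivalent
  invariant form γ_oct = (2/√3)·‖dev ε‖_F, which avoids a per-voxel
  eigendecomposition; the test suite verifies it against a literal
  eigenvalue-based computation on random tensors to 1e-10. OSS summarizes
  "the maximum shear strain regardless of direction", which is why it is the
  primary vulnerability variable.
* **Maximum principal strain (MPS)**, the largest eigenvalue ε₁, mixes shear
  and longitudinal strain. It is computed with the closed-form trigonometric
  solution for symmetric 3×3 eigenvalues, vectorized over voxels. OSS and
  MPS are strongly correlated on generic strain fields (checked as a sign
  property in the tests, not as a numeric target, since the printed
  correlation of any particular dataset is data-specific).

From the complex shear modulus G* = G′ + iG″ the **damping ratio** is
ξ = G″/(2G′). The notation "G″/2G" appears in parts of the MRE literature
with the storage modulus in the denominator; we implement the standard
definition G″/(2G′), consistent with G* notation. Storage modulus measures
elastic energy storage (stiffness), ξ measures relative energy dissipation.

## 2. Normative map and the high-strain region

Each subject's OSS map is z-scored *within subject* across all in-mask
voxels (sample SD, n−1 denominator, matching common statistical software).
Z-scoring before averaging removes per-subject scale differences (driver
coupling, global stiffness) so that the normative map reflects *relative*
strain concentration; the pipeline also exposes an `average_then_zscore`
switch because the alternative ordering is defensible when subjects share a
scale. The normative map is the voxelwise mean of the z maps.

The high-strain (HS) region is defined by a voxelwise one-sample t-test
(H₀: mean OSS z = 0, df = n−1) with Benjamini–Hochberg FDR over in-mask
voxels, thresholded jointly at **q < 0.05 and t ≥ 4**. Design choices:

* p-values are two-sided by default (one-sided is available); the t ≥ 4 gate
  enforces positivity either way, so the joint rule does not depend on the
  sidedness convention.
* zero-variance (degenerate) voxels are retained with t = 0, p = 1 rather
  than dropped, so the multiplicity count m is reproducible.
* FDR is computed strictly over in-mask voxels; the mask is a required
  input, never inferred from the data.
* no smoothing or cluster-extent inference is applied; a minimum
  cluster-size option exists (`min_cluster`) but defaults to 1 and is a
  reporting convenience only.

The low-strain (LS) region is the complement of HS within the brain mask, so
HS and LS always partition the mask (asserted on every construction).
Leave-one-out cross-validation rebuilds the statistics and mask on n−1
subjects and extracts the held-out subject's HS/LS mean OSS; the paired
Wilcoxon signed-rank test (exact p for n ≤ 25 after zero-drop, normal
approximation with continuity correction above; zeros dropped per Wilcoxon's
original prescription) tests HS > LS generalization.

## 3. AFD from single-shell diffusion MRI

The pipeline assumes co-registered, preprocessed DWI (distortion/eddy/bias
correction and registration are upstream concerns, out of scope).

* **Tensor fit**: weighted log-linear least squares (OLS followed by one
  reweighting step with squared predicted signals), FA/MD from eigenvalues,
  negative eigenvalues clamped to zero for FA with a warning counter.
* **Response calibration**: up to 300 voxels with FA > 0.7 (highest first);
  each voxel's b0-normalized signal is rotated so its principal eigenvector
  points to the pole and projected onto the zonal (m = 0) even spherical
  harmonics; coefficients are averaged. Normalizing the response so that its
  l = 0 term reproduces the mean high-FA signal amplitude keeps AFD units
  consistent across subjects, given consistent scaling.
* **CSD**: the fODF is expanded in a real, orthonormal, even-order spherical
  harmonic basis (the convention identifier is stored with every fODF field,
  because mixing basis conventions silently corrupts the l = 0 scaling). The
  axially symmetric response enters through the rotational convolution
  kernel √(4π/(2l+1))·r_l. Non-negativity is enforced iteratively: fODF
  amplitudes on a fixed 300-direction Fibonacci sphere falling below
  τ = 0.1 of the mean initial amplitude (initialization: unconstrained fit
  truncated at order 4) are penalized with weight λ = 1, until the
  constraint set stops changing or 50 iterations; non-convergent voxels are
  retained and flagged. Defaults lmax = 8 (45 coefficients, supported by
  ~60–64 directions; lmax auto-lowers with a warning when directions are
  scarce), τ and λ follow the single-shell CSD literature and are exposed in
  the configuration because the source analyses do not pin them down. The
  constraint sphere is generated in code (a deterministic Fibonacci spiral)
  rather than shipped as a data file; exact rotational equivariance holds up
  to this discretization (verified at machine precision when the constraint
  sphere is rotated with the problem, and to ~1e-3 with the fixed set).
* **AFDtotal** is the l = 0 coefficient c₀₀ of the fODF; in the orthonormal
  basis the spherical mean of the fODF is c₀₀/√(4π). Signals are divided by
  the mean b0 per voxel before deconvolution (removes receiver-gain
  differences and fixes AFD units); this normalization is on by default and
  a documented switch in concept — group statistics are invariant to global
  gain either way.

The independent oracle for the deconvolution is a dense-grid non-negative
least-squares deconvolution (fODF as non-negative delta weights on a
400-direction grid against the axially symmetric response profile),
implemented only in the tests; package AFD correlates > 0.99 with it on 500
mixed synthetic voxels.

## 4. Strain-stratified group statistics

The normative OSS z map is discretized into bins of width 0.25 z units with
edges anchored at integer multiples of the width (the anchoring makes bin
identity reproducible across cohorts; the observed z range alone would not).
Intervals are half-open [edge, edge+width) with a closed top edge. Per
subject, mean AFD is computed within each bin; bins with fewer than 10
voxels are dropped (`min_voxels_per_bin`, configurable — the subject-level
mean of a nearly empty bin is noise).

The central model is

```
mean_afd ~ group * oss_center + (1 | subject)
```

with the bin center as a continuous predictor, centered at its grand mean so
the group main effect is the group difference at mean strain. Estimation is
REML via `lme4`, Satterthwaite p-values via `lmerTest`, Wald 95% CIs.
Because each response value is a mean over `n_voxels` voxels, rows are
weighted by `n_voxels` by default: the residual variance of a bin mean
scales as σ²/n_voxels, and the weighted model reproduces that structure
exactly, which is what makes the null calibration of the interaction test
land at its nominal level (verified over 1,000 null replicates in the
acceptance suite). Random-effect structure is a subject intercept only,
matching the model formula; within-subject bin correlation beyond the
intercept is not modeled. Singular fits are flagged but fixed effects are
still reported.

Sign convention: the reported `interaction` is the **control-minus-mTBI
slope difference** (positive when controls gain more AFD per unit strain
than mTBI). With control slope ≈ 0.041 and mTBI slope ≈ 0.029 AFD units per
OSS z in the subacute/chronic preset this gives +0.012; the acute preset
(0.041 vs 0.043) gives −0.002. The group factor is coded internally with
control as the reference level; the reported quantities are linear
combinations, so the convention is a presentation choice made to match the
direction in which the phase-specific fits are usually quoted.

ROI-level statistics: per subject, mean AFD in HS and LS and their ratio
AFD_HS/AFD_LS (subjects with non-positive LS means are excluded from ratio
analyses with a log message). The 2×2 mixed-design ANOVA treats group as
between-subjects and region as within-subjects, with the textbook
sums-of-squares decomposition (cross-checked against `aov()` error strata in
the tests, balanced and unbalanced); the ratio test is a directed Welch
two-sample t (equal-variance optional). The ANOVA uses raw AFD with region
as a repeated measure; the ratio analysis is the separate directed test.
Sex-stratified contrasts re-run the ratio test per stratum, skipping strata
with fewer than 2 subjects per group.

## 5. The synthetic-data generator

The generator produces co-registered cohorts with known ground truth; it is
the package's test bed, not a brain simulator. Its defaults define the study
conditions used by the tests and the acceptance script:

* **Grid**: 48×56×48 voxels at 2 mm (tests and the acceptance script use
  32×36×32 or 24³ where the statistics do not need the full grid; all sizes
  are stated at the call site). An ellipsoidal mask stands in for the brain.
* **Normative OSS field**: baseline 1.0 (arbitrary strain units — all
  downstream analysis z-scores within subject, so only relative structure
  matters) + a smooth mean-zero background (SD 0.04, FWHM 12 mm) + three
  well-separated hard spheres of radius ≈ 10% of the grid extent with graded
  amplitudes 1.6/1.2/0.8. The graded amplitudes spread the planted structure
  over several z bins, giving an in-mask z range of roughly −0.7 to +3.7 —
  comparable to the −1..+4 range typical of normative strain maps. The blob
  union is the ground-truth high-strain region. Blobs use hard edges so that
  plant-recovery Dice is a sharp criterion rather than an artifact of a
  fuzzy boundary. The background SD is deliberately small relative to the
  per-subject noise: shared background structure is a true (if small) signal
  to the one-sample t-test, and making it large would conflate "false
  positives" with faithfully detected background. Null cohorts therefore set
  the background SD to zero, making the voxelwise null exactly true.
* **Subject MRE realizations**: normative field + a per-subject smooth noise
  field (SD 0.15, same FWHM). The magnitude of within-subject strain noise
  in real data is not well pinned down; 0.15 (≈0.4 z) was chosen once so
  that planted effects are recoverable at realistic cohort sizes, and the
  tests include a monotonicity check (recovery never improves with more
  noise) rather than claims about empirical variance.
* **Tensor synthesis**: each voxel's tensor is a unit deviatoric template
  u u′ − w w′ (eigenvalues 1, 0, −1) scaled so its OSS equals the target,
  carried through a smoothly varying rotation field. This reproduces the OSS
  map exactly while exercising the eigenvalue path with non-axis-aligned
  tensors. Raw strain tensors are not available in the source material; this
  construction is the minimal field consistent with a given OSS map.
* **Moduli**: G′ = 2400 Pa baseline with +600 Pa inside the true HS region
  (plus 30 Pa noise); ξ = 0.25 baseline with −0.08 inside (plus 0.005
  noise); G″ = 2 G′ ξ. Magnitudes are typical for brain tissue at 50 Hz;
  the increments make the planted directions (HS stiffer, HS less
  dissipative) hold in every subject, which is the property the tests
  assert.
* **AFD cohorts**: AFD(v, s) = 0.5 + slope_group·OSSz(v) + b_s + e(v, s),
  with b_s ~ N(0, 0.05²) between subjects and e ~ N(0, 0.15²) per voxel.
  Presets: `subacute_chronic` (slopes 0.041/0.029), `acute` (0.041/0.043),
  `null` (identical groups), `hs_deficit` (equal slopes plus a 0.02 AFD
  decrement confined to the true HS region in mTBI — the mechanism for
  acute-phase, ROI-confined deficits; outside the HS region the acute
  preset plants no group offset). Sex alternates F/M and enters no
  generative equation: sex-stratified analysis is purely a grouping feature.
* **DWI**: multi-compartment cylindrically symmetric tensors (axial
  1.7e-3, radial 0.3e-3 mm²/s) plus an isotropic remainder (1.0e-3 mm²/s),
  Rician noise at the stated SNR, Fibonacci-hemisphere gradient schemes
  (64 directions at b = 1000 s/mm² plus b = 0 by default).

What the generator does **not** emulate: real anatomy and tissue interfaces,
skull/CSF geometry, wave propagation physics, registration error, spatially
correlated AFD noise, and partial-volume boundaries. Passing tests therefore
demonstrate that the *pipeline* is correct and calibrated under its stated
model, not that the biological effect sizes are realistic beyond the planted
values.

## 6. Numerical choices and degenerate inputs

* Eigenvalue ordering is descending with ties allowed; isotropic voxels take
  the analytic branch (p = 0) in the MPS solver.
* `bh_fdr()` delegates to `stats::p.adjust(method = "BH")`; the tests hold
  it to exact equality with a literal step-up implementation.
* Constant maps cannot be z-scored (error); zero-variance voxels in the
  group t-test are degenerate (t = 0, p = 1, warned, retained).
* An empty HS mask is an error that names the thresholds; LOO folds with
  empty HS masks are excluded and reported.
* Paired contrasts with identical differences (zero SD) are degenerate
  errors rather than infinite t values.
* Binning anchors edges at integer multiples of the width; the top edge is
  closed so the maximum voxel is always binned; the voxel count is conserved
  across bins before the minimum-voxel filter.
* All generator randomness flows through explicit integer seeds; identical
  (spec, seed) pairs are bit-identical, and the RNG state of the caller is
  restored afterwards.
* Pipeline provenance records hash the configuration after key sorting, so
  the hash is stable under key reordering.

## 7. Problem sizes used by the tests and acceptance script

Parameter recovery runs 50 replicates per preset on a 32×36×32 grid
(n = 31+31 subacute/chronic, 15+29 acute); null calibration runs 1,000
replicates (n = 10+10) and power 500 replicates (n = 15+29) on a 24³ grid;
plant recovery and leave-one-out use the full 48×56×48 grid with n = 30 and
n = 20. These sizes were chosen so the whole suite runs comfortably on one
CPU while keeping Monte-Carlo error well inside the asserted tolerances (for
50 replicates the SE of the mean interaction is about 0.4% of its value,
versus a 10% acceptance band).

## 8. Known limitations

* Single-tissue, single-shell CSD only; multi-shell/multi-tissue variants,
  fixel segmentation and tractography are out of scope, as are claims about
  intra-axonal volume fractions at b = 1000 s/mm².
* The mixed model treats bins as exchangeable given the subject intercept;
  spatially correlated residuals between adjacent bins are not modeled.
* No cluster-level or permutation inference for the voxelwise map.
* The package performs no registration: all volumes must already share one
  grid and affine, and inputs violating that are rejected rather than
  resampled.
* `run_pipeline()` orchestrates the simulate mode end to end; real-data
  studies ingest co-registered NIfTI volumes with `read_volume()` and call
  the stage functions directly.
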