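---
title: "Whole-liver tumor burden biomarkers and survival modeling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-liver tumor burden biomarkers and survival modeling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wltb)
```

## Scope and model

`wltb` quantifies the *whole liver tumor burden* (WLTB) — the union of all
segmented liver metastases of one patient — from a contrast-enhanced CT
volume plus co-registered label volumes, and asks whether those imaging
biomarkers improve survival prediction in metastatic pancreatic cancer over
established clinical prognostic models. The package covers the full chain:

1. a synthetic phantom cohort generator (liver, lobes, lesions, HU noise,
   clinical covariates, proportional-hazards survival),
2. thirteen quantitative imaging biomarkers (QIBs) per subject,
3. univariable Cox screening, two clinical baseline models, extension by
   AIC backward elimination with forced-in clinical terms, a nested
   likelihood-ratio (LR) comparison, Harrell's C-index, and median-split
   risk stratification with Kaplan-Meier curves and the log-rank test.

The thirteen QIBs are: mean lesion attenuation (HU); absolute WLTB volume
(cm³) and WLTB volume as a percentage of liver volume; the tumor burden
score TBS = √(N² + D²), with N the lesion count and D the diameter of the
largest lesion in cm; bilobar disease (metastases in both functional liver
lobes); the four-feature prognostic radiomics signature — first-order
energy, shape compactness, gray-level run-length-matrix (GLRLM) gray-level
nonuniformity (GLN), and the same nonuniformity on a wavelet sub-band —
and the geometric metastatic spread: per-axis extents MSx, MSy, MSz (cm)
plus the surface-area-to-volume ratio SA/V (1/cm) of the lesion union.

## The phantom generator: what it emulates, and what it does not

The generator's defaults are the study conditions the analysis is designed
for, anchored to published cohort characteristics of metastatic pancreatic
cancer with liver metastases:

* **Cohort size** 75 subjects.
* **Lesion count** per subject: zero-truncated negative binomial
  (size 0.8, mean 9, capped at 113), giving a median of 7 lesions and a
  long right tail — the dispersion seen in real metastatic burden counts.
* **Lesion radii**: log-normal with median 5 mm (sdlog 0.45), floored at
  just over one voxel; generated lesions that overlap merge and are
  *recounted* as 26-connected components, because a segmentation pipeline
  counts observed lesions, not generative events.
* **Anatomy**: the liver is an ellipsoid (default semi-axes 80 × 55 × 45 mm)
  with per-subject log-normal size variability (sd 0.08). The size
  variability matters statistically: with a fixed liver volume, relative
  tumor volume would be exactly proportional to absolute volume and every
  multivariable design containing both would be singular. The two lobes
  are split by a sagittal-oblique plane through the liver centroid
  (default 20°). Real functional-lobe anatomy (Cantlie's line) is out of
  scope — the analysis consumes lobe labels, it never infers them.
* **Intensities**: portal-venous parenchyma ~N(105, 10²) HU, hypodense
  lesions ~N(65, 10²) HU, air −1000 HU, independent voxel noise. An
  optional low-pass random field (`texture_sigma_mm`) adds spatially
  correlated texture so run-length features are non-degenerate when that
  is the property under study.
* **Survival**: event times follow a Cox model whose linear predictor is
  built from *extracted* features (default drivers: TBS, bilobar disease,
  log CRP, coefficients 0.5/0.6/0.4 per standardized covariate) over an
  exponential baseline with rate ln 2 / 10 per month, i.e. a 10-month
  median survival; censoring is administrative (uniform cutoff calibrated
  to an 8% censoring fraction). Continuous covariates are centered and
  scaled before the coefficients apply; binary covariates are centered
  only, so the cohort-level median survival keeps its nominal value.
* **Clinical covariates**: ECOG 0/1/2/3 with probabilities
  0.44/0.507/0.04/0.013; log-normal CRP (median 1.0 mg/dl), bilirubin
  (median 0.6 mg/dl) and CA19-9 (median 463 U/ml, heavy tail).

What phantoms deliberately do **not** model: CT physics (beam hardening,
reconstruction kernels), respiratory motion, contrast-phase timing,
non-ellipsoidal organ shape, infiltrative lesion margins, and intra-lesion
texture heterogeneity beyond the optional noise field. Passing tests on
phantoms therefore demonstrate *definitional and statistical correctness*
of the feature extractors and models — not that the absolute feature
values match any particular scanner or segmentation software. Published
absolute values from real cohorts depend on preprocessing details
(resampling, gray-level ranges, wavelet normalizations) that differ
between toolkits; only definitional correctness is testable without the
original data.

## Geometry: numerical choices

**Surface area.** SA/V and compactness need the surface area of a binary
voxel region. Counting exposed voxel faces overestimates the area of
smooth shapes by up to ~50% (a digitized sphere's staircase), so the
default estimator extracts an iso-surface: the mask is Gaussian-smoothed
with σ = 0.75 voxel per axis (anti-aliasing) and the 0.5 level set is
triangulated by *marching tetrahedra* — each grid cell is split into six
tetrahedra around its main diagonal; inside a tetrahedron the level set of
the linear interpolant is a single triangle or a quad, so the
triangulation follows from first principles without case tables. The
σ = 0.75 voxel default balances staircase overestimation (no smoothing:
~ +10% on spheres) against curvature shrinkage (one full voxel: −5% or
worse for small lesions); at that setting digital spheres of radius
10–15 mm at 1 mm spacing reproduce the analytic area within ~1–2%.
Regions so small that smoothing pulls them entirely below the iso-level
fall back to the unsmoothed binary surface. Voxel-face counting remains
available via `method = "voxel"` for comparison.

**Compactness** is `V / (√π · A^{3/2})` (dimensionless, scale-invariant,
maximal for a sphere at 1/(6π) ≈ 0.05305), computed from the same mesh.

**Lesion diameter** is the 3D maximum pairwise distance between voxel
centers in physical mm. The maximizing pair always lies on the lesion
boundary, so only 6-boundary voxels are searched (exact, chunked to bound
memory). An axial-only (in-plane) variant is exposed for RECIST-style
measurements; the 3D default follows the tumor-burden-score literature,
which does not restrict the plane.

**Bilobar disease** is decided at voxel level: a single lesion straddling
the lobe plane counts, because the definition is presence of metastases in
both lobes, not a per-lesion assignment.

**Metastatic spread** (MSx/MSy/MSz) is the max-minus-min coordinate of
lesion voxel centers per axis (cm), with a centroid-based variant behind
an option; the two coincide for point-like lesions and differ by at most
one lesion diameter. Axis semantics are fixed package-wide:
x = left–right, y = anterior–posterior, z = cranio-caudal, recorded in
every cohort manifest.

**Zero-lesion subjects** yield missing-value sentinels (`NA`) with a
warning, never fabricated zeros; cohort-level exclusion of such subjects
is the ingest stage's job, mirroring how empty-burden patients are
excluded from real cohorts.

## Texture features: conventions that change numbers

* **Energy** is the sum of squared *raw* HU over the region — no intensity
  shift. Some toolkits add a constant offset before squaring, which
  changes values by orders of magnitude; the convention is fixed and
  documented here.
* **Discretization** uses a fixed bin width of 25 HU starting at the
  region minimum — recommended practice for calibrated CT units. The
  width is a config default, not a constant.
* **GLRLM GLN** accumulates maximal same-bin runs along the 13 unique 3D
  directions; by default run matrices are *merged* across directions
  before GLN = Σᵢ(ΣⱼR(i,j))²/ΣᵢⱼR(i,j); per-direction averaging is the
  alternative aggregation. A single-bin region degenerates to the total
  run count (documented, returned as such).
* **Wavelet nonuniformity** applies a single-level *undecimated*
  (stationary) separable 3D transform — Coiflet-1 by default, sub-band
  HLH over (x, y, z), symmetric boundary extension — so the sub-band
  stays voxel-aligned with the mask, then computes GLN on the filtered
  values with the same discretization. Family and sub-band are config;
  the undecimated choice avoids the mask-alignment ambiguity that
  decimated transforms create.

## Survival pipeline: design choices

* **Ties**: Efron approximation (the survival literature's default).
* **Baseline clinical models**: model 1 uses ECOG 0 vs ≥1, log CRP
  (mg/dl), log bilirubin (mg/dl), with an epsilon offset (logged) for
  nonpositive lab values; model 2 uses three inclusive binary indicators:
  ECOG ≥ 2, CA19-9 ≥ 1000 U/ml, CRP ≥ 5. The CRP cutoff is exposed as a
  parameter because published variants state it in mg/l while applying it
  to mg/dl-scaled data; this package stores CRP in mg/dl and defaults the
  cutoff to 5 on that scale.
* **Screening** keeps features with univariable Wald p < 0.2 — a
  deliberately permissive gate whose null pass rate is, by construction,
  ~20% (verified by simulation in the test suite).
* **Backward elimination** starts from baseline + all screened candidates
  and repeatedly removes the single candidate whose removal most lowers
  the AIC, stopping at a local minimum; clinical terms are never
  removable, which guarantees the final model nests the baseline for the
  LR test. AIC ties are broken by removing the larger-Wald-p feature
  (deterministic, recorded in the elimination trace). Candidates exactly
  collinear with the running design are dropped up front with a warning.
  A known statistical property, worth stating: under the null a noise
  covariate's χ² statistic exceeds AIC's 2-unit penalty with probability
  P(χ²₁ > 2) ≈ 0.157, so AIC elimination retains pure noise in roughly
  one run in six, and the screen-then-eliminate cascade in roughly one in
  ten — AIC is a prediction-oriented criterion, not a significance test.
* **Risk stratification** splits the cohort at the *median of the linear
  predictor* (the standard reading of a median split); the alternative
  reading — classify by whether model-predicted median survival exceeds
  the cohort's observed median — is implemented behind
  `split = "predicted_survival"`.
* **Correlation report**: Spearman by default (rank-invariant, suited to
  heavy-tailed markers like CA19-9), Pearson available; ordering by
  average-linkage clustering on 1 − |ρ|.
* **Missing data**: complete-case per analysis with the per-model n
  logged; no imputation.

## Reproducibility

All randomness flows from one root seed through named child streams (an
FNV-hash of seed + stage label), so phantom anatomy, clinical covariates
and survival draws are independent streams: changing the radiomics
configuration cannot perturb the survival simulation, and any subject can
be regenerated in isolation. Pipelines rerun with the same configuration
produce byte-identical CSVs; each run manifest records an 8-hex-digit
hash of the canonicalized configuration.

## Problem sizes used in the shipped checks

The test suite exercises phantoms on a 64 × 64 × 36 grid at
2.5 × 2.5 × 3.5 mm (a coarser cousin of the 96 × 96 × 48 default), 100
subjects for the pipeline-level properties, 20 survival replicates for
the improvement properties, and 100–1000 Monte-Carlo replicates for the
calibration checks (screen null rate, LR type-I error, log-rank
uniformity); `scripts/acceptance.R` runs the default 75-subject
conditions end to end. These sizes were chosen so every statistical
assertion has enough replicates for its stated tolerance.

## Known limitations

* Phantom lesions are spheres; shape-feature *distributions* (compactness,
  SA/V) are therefore narrower than in real cohorts.
* The lobe split is a plane; straddling-lesion frequencies depend on that
  simplification.
* Absolute texture values are convention-bound (bin width, wavelet
  family, aggregation); cross-toolkit comparisons need matched configs.
* The LR comparison is in-sample, as in the modeling setting it mirrors;
  no external validation or optimism correction is attempted.
* Proportional-hazards diagnostics beyond the simulation ground truth are
  not part of the pipeline.
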