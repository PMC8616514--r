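# wltb — whole-liver tumor burden imaging biomarkers and survival modeling

Metastatic pancreatic cancer carries a dismal prognosis, and the clinical
scores used to stratify patients (performance status plus serum markers
such as CRP, bilirubin and CA19-9) have limited discriminative power.
`wltb` implements an imaging-based complement: it treats the **whole
liver tumor burden (WLTB)** — the union of all segmented liver
metastases of one patient — as a single region of interest on a
contrast-enhanced CT, computes thirteen quantitative imaging biomarkers
(QIBs) from it, and tests whether adding them to the clinical Cox models
improves survival prediction.

The package is aimed at imaging/biostatistics researchers who have (or
want to simulate) 3D CT volumes with co-registered liver, lobe and
lesion label maps plus a clinical table, and want a reproducible
end-to-end pipeline from voxels to Kaplan–Meier curves.

## The biomarkers and the statistics

Per subject, from an image volume `I` (HU) and lesion union `M`:

* mean attenuation over `M` (HU); WLTB volume (cm³), absolute and as %
  of liver volume;
* **tumor burden score** `TBS = sqrt(N² + D²)` — `N` lesions, `D` =
  largest lesion diameter (cm, 3D maximum pairwise distance);
* **bilobar disease** — lesion voxels in both functional lobes;
* the four-feature radiomics signature: first-order **energy**
  `Σ I(v)²`; **compactness** `V/(√π A^{3/2})` (sphere-maximal at 1/6π);
  **GLRLM gray-level nonuniformity** `Σᵢ(ΣⱼR(i,j))²/ΣᵢⱼR(i,j)` over the
  13 unique 3D run directions; the same nonuniformity on an undecimated
  coif1 wavelet sub-band (HLH);
* **geometric metastatic spread**: per-axis extents MSx/MSy/MSz (cm) and
  surface-area-to-volume ratio SA/V (1/cm) of the lesion union.

The survival stage fits two published-style clinical baselines
(model 1: ECOG 0 vs ≥1, log CRP, log bilirubin; model 2: ECOG ≥2,
CA19-9 ≥1000 U/ml, CRP ≥5), screens the 13 QIBs univariably at Wald
p < 0.2, extends each baseline with the screened candidates via AIC
backward elimination (clinical terms forced in), compares baseline vs
extended with the nested likelihood-ratio test and Harrell C-indices,
and stratifies the cohort at the median linear predictor into high/low
risk groups (Kaplan–Meier + log-rank).

Because no public cohort accompanies this problem, the package ships a
first-class synthetic module: ellipsoidal two-lobe liver phantoms with
hypodense spherical lesions (lesion counts zero-truncated negative
binomial, median 7, up to 113), clinical covariates with realistic
distributions, and survival times drawn from a proportional-hazards
model whose linear predictor is built from the *extracted* features —
so every downstream stage has a known ground truth.

## Worked example

Simulate a 60-subject cohort on a coarse grid, extract all features, and
run the full analysis against clinical baseline model 1:

```r
library(wltb)

cfg <- pipeline_config(
  seed    = 42,
  phantom = phantom_config(subjects = 60, grid_shape = c(64L, 64L, 36L),
                           voxel_spacing = c(2.5, 2.5, 3.5),
                           liver_semi_axes = c(70, 48, 40)),
  baselines = "haas")

cohort <- simulate_cohort(cfg)
head(cohort$features[c("subject_id", "volume_cm3", "tbs", "bilobar",
                       "sa_v_per_cm")], 4)
#>   subject_id volume_cm3  tbs bilobar sa_v_per_cm
#> 1       S001       1.03 2.25   FALSE        3.12
#> 2       S002       1.75 4.18    TRUE        2.47
#> 3       S003       1.68 1.73   FALSE        3.34
#> 4       S004       4.02 3.44    TRUE        3.13

an <- run_analysis(cohort$features, cohort$clinical, cfg)
an$models$haas$baseline
#> <cox_fit> n = 60 , events = 55 , C-index = 0.639 , AIC = 348.8
#>           name coefficient    se    hr hr_lo hr_hi  wald_p
#>     ecog_1plus     -0.3880 0.303 0.678 0.374  1.23 0.20000
#>        log_crp      0.5250 0.177 1.690 1.200  2.39 0.00294
#>  log_bilirubin      0.0605 0.221 1.060 0.689  1.64 0.78400

an$models$haas$comparison
#> <model_comparison> LR = 53.948 on 5 df, p = 2.15e-10 ; C-index 0.639 -> 0.822

an$models$haas$stratification
#> <risk_stratification> log-rank p = 1.14e-10 ; median survival: low 27, high 3.6 months
```

Reading: the clinical baseline alone discriminates survival with
C = 0.639; adding the retained imaging features (here WLTB volume,
bilobar disease, energy, compactness, GLRLM nonuniformity survived
backward elimination) raises it to C = 0.822, the nested LR test is
decisive, and the median-split risk groups separate 3.6 vs 27 months of
median survival — the hazard in this simulation really is driven by
TBS, bilobar disease and log CRP, so that is the recovery one should
see.

`run_pipeline(cfg, out_dir = "out")` performs the same steps and writes
`features.csv`, `clinical.csv`, `table2.csv` (univariable screen),
`table3.csv` (baseline + extended fits with C-indices and LR p),
`stratification.csv`, Kaplan–Meier and correlation-heatmap PNGs, and a
JSON run manifest with a configuration hash; repeated runs with the same
seed are byte-identical. A thin command-line wrapper
(`inst/scripts/wltb.R`) exposes `simulate`, `extract`, `fit`, `run` and
`validate` subcommands over YAML configs, and `ingest_external()`
validates real NIfTI cohorts (grid/spacing agreement, lesions inside the
liver, empty-burden exclusions) before the same analysis.

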