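# vrsquant

Automated quantification of visible Virchow–Robin spaces (VRs, also called
perivascular spaces) on axial T2-weighted MRI, together with the cohort
statistics used to relate VRs burden to simple-febrile-seizure duration in
young children.

Enlarged perivascular spaces are CSF-filled channels around perforating
vessels. On T2-weighted images they appear as bright linear or circular
structures, and their count and volume in the white matter at and above
the lateral ventricles are used as an imaging proxy for glymphatic
function. `vrsquant` provides, in one package:

* **Phantoms** — T2-like digital head phantoms with exactly known
  embedded tubular/circular VRs structures and Rician (magnitude-MR)
  noise, so every stage is testable without clinical data.
* **Quantification** — brain extraction, three-class intensity
  segmentation (WM / GM / CSF), a supraventricular white-matter region of
  interest, multi-scale 2D Frangi vesselness per axial slice,
  thresholding, 26-connected component counting and volumetry.
* **Synthetic cohorts** — subject tables with configurable per-group
  means ± SD, truncation bounds and cross-correlations between seizure
  duration, course after onset, VRs count and VRs volume.
* **Statistics** — two-sided Mann–Whitney U comparisons at a
  Bonferroni-adjusted level (.05/3 → .017), Pearson correlation panels,
  and LOESS-based detection of a seizure-duration cutoff.

## The core operator

For each axial slice and each scale σ (mm), the Gaussian-derivative
Hessian is computed, γ-normalised by σ², and its eigenvalues ordered so
|λ₁| ≤ |λ₂|. The bright-tube vesselness is

```
V = 0                                             if λ₂ ≥ 0
V = exp(−R_B² / 2β²) · (1 − exp(−S² / 2c²))       otherwise
```

with blobness `R_B = λ₁/λ₂`, structureness `S = √(λ₁² + λ₂²)`, β = 0.5,
and `c` resolved adaptively per slice as half the maximum γ-normalised
Hessian norm across the scale set {0.375, 0.75, 1.125, 1.5} mm. The
per-pixel maximum over scales is thresholded (default 0.25) inside the
supraventricular ROI, and 26-connected components of at least 2 voxels
become the reported VRs. All defaults are configurable and recorded in
the provenance of every metric.

## Worked example

```r
library(vrsquant)

# a noisy phantom with 25 known perivascular structures
cfg <- phantom_config(
  structures = random_vrs_structures(phantom_config(), 25, seed = 11),
  seed = 11)
sim <- simulate_phantom(cfg)
sim$truth$vrs_count        # 25 structures, 519.75 mm^3 ground truth
run_subject_pipeline(sim$volume)
#> <vrs_metrics>
#>   VRs count : 25
#>   VRs volume: 477.00 mm^3
#>   WM volume : 285471 mm^3
#>   Brain vol : 491724 mm^3
```

The pipeline recovers the embedded count exactly and the volume within
~8% at the default noise level. On the statistics side:

```r
coh <- generate_cohort(cohort_config(seed = 1))   # 30 / 40 / 35 subjects
pairwise_group_comparisons(coh, "vrs_count")
#> Pairwise Mann-Whitney comparisons (adjusted alpha .017):
#>      metric  group1  group2 n1 n2     U            p p_rendered significant
#> 1 vrs_count  SFS>5M SFS<=5M 30 40  56.0 1.115671e-10      <.001        TRUE
#> 2 vrs_count  SFS>5M control 30 35  64.5 1.419772e-09      <.001        TRUE
#> 3 vrs_count SFS<=5M control 40 35 470.5 1.500902e-02       .015        TRUE
```

The long-seizure group's elevated VRs counts reproduce as highly
significant against both other groups. Correlations inside that group
come out positive with duration and negative with the seizure-to-scan
interval, matching their configured targets:

```r
correlation_panel(coh, "SFS>5M")
#>    group         var1           var2          r      p_rendered   n
#> 1 SFS>5M duration_min      vrs_count  0.7546146        <.001     30
#> 3 SFS>5M  course_days      vrs_count -0.8483406        <.001     30
```

A command-line surface wraps the same functions
(`simulate-phantom`, `simulate-cohort`, `quantify`, `stats`,
`end-to-end`); see `system.file("cli", "vrsquant", package = "vrsquant")`.

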