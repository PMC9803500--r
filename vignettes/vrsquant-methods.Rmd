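---
title: "Models and methods behind vrsquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vrsquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vrsquant)
```

`vrsquant` quantifies visible Virchow–Robin (perivascular) spaces on
axial T2-weighted volumes and reproduces the cohort statistics that
relate perivascular-space burden to febrile-seizure duration. Because no
clinical images ship with the package, every stage is exercised on
synthetic data whose ground truth is exact. This vignette describes the
models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data can and cannot establish about real
scans.

## 1. The image phantom

The phantom is a deliberately minimal T2-like head: a brain ellipsoid
(white-matter core, grey-matter shell) over a near-zero background, two
paramedian ellipsoidal lateral ventricles filled with CSF, and a list of
perivascular structures painted at CSF intensity inside the
supraventricular white matter. Intensities default to WM 100, GM 130,
CSF 200 — ordered as T2 contrast requires — with no within-class
variation before noise. The default grid is 160 × 160 × 24 voxels at
0.75 × 0.75 × 4 mm (a 120 mm field of view at the acquisition's pixel
size and slice thickness, so per-test runtimes stay in seconds);
`phantom_config(full = TRUE)` switches to the full 320 × 320 acquisition
matrix (240 mm field of view) at identical spacing.

Perivascular structures are cylinders of radius 0.75 mm (one in-plane
pixel): *linear* ones with a free in-plane orientation and lengths of a
few millimetres, *circular* ones crossing the slice plane so they read
as disks. Rasterisation is by voxel-centre-in-cylinder, so the true
volume is exactly (labelled voxels) × 2.25 mm³ — the conservation the
tests assert. The random placement helper keeps structures inside the
supraventricular white matter, enforces a *capsule* (axis-segment)
separation rather than a centre separation — elongated structures with
distant centres can still touch at their endpoints and would otherwise
merge into one component — and keeps every structure voxel clear of a
dilated ventricle guard, because a CSF-bright voxel 26-adjacent to the
ventricles would be absorbed into the ventricle component and shift the
detected boundary slice.

Noise follows the magnitude-MR (Rician) model: each voxel v becomes
`sqrt((v + n1)^2 + n2^2)` with n1, n2 ~ N(0, σ²), default σ = 5 — about
20:1 signal-to-noise in white matter, a mild, realistic level. At zero
signal this is a Rayleigh law with mean σ√(π/2), which the tests verify
in closed form.

**What the phantom does not emulate:** cortical folding, partial-volume
gradients, bias fields, motion, multi-contrast appearance, or the true
morphology of perivascular spaces (curved, tapering, clustered around
perforators). Passing the recovery suites therefore shows the pipeline
is correct *given its model assumptions*, not that it matches
radiologist readings on clinical scans.

## 2. Preprocessing

Brain extraction is a single global Otsu threshold, the largest
26-connected component, and per-slice hole filling. One global threshold
matters: per-slice thresholds on a volume whose top slices contain only
air would adapt to noise and admit spurious foreground. Tissue
segmentation is 1-D k-means (k = 3, 10 restarts, seed-controlled) on
intensities inside the brain mask, classes named by ascending mean —
on T2, WM < GM < CSF. On the noiseless phantom this recovers the classes
exactly; at default noise the per-class Dice stays above 0.90.

Ventricles are the CSF components whose in-plane centroid lies in the
central third of the field and whose volume exceeds 500 mm³ (small
CSF-bright perivascular structures are orders of magnitude below this).
The counting region is, on every slice at or above the superior-most
ventricle slice `z_v` (inclusive — the most literal reading of "at and
above the ventricular level"), the filled white matter minus the
ventricles. Filling is essential: visible perivascular spaces are
CSF-bright and segment as CSF, so taking raw WM voxels would exclude
precisely the structures being counted. Slice index increases
superiorly by convention; NIfTI input is reoriented to RAS+ on load to
guarantee it.

## 3. Multi-scale 2D vesselness

Filtering is two-dimensional, per axial slice: with 4 mm slices against
0.75 mm pixels, through-plane derivatives are unreliable, and the 2D
form needs no third eigenvalue. At scale σ (in mm, converted to pixels
through the spacing so behaviour is resolution-independent) the Hessian
is computed by sampled Gaussian-derivative convolution with symmetric
boundary handling and γ = 1 scale normalisation (multiply by σ²), the
standard choice for cross-scale comparability. The discrete kernels are
moment-corrected — zero DC, exact on linear and quadratic polynomials —
because at the smallest default scale (0.375 mm = half a pixel) naively
sampled second-derivative kernels respond to constant intensity.

Eigenvalues come from the closed 2 × 2 form, ordered |λ₁| ≤ |λ₂| with
exact ties broken by λ₁ ≥ λ₂, and the bright-tube measure is

$$V = \exp\!\left(-\frac{R_B^2}{2\beta^2}\right)
      \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
  \qquad R_B = \lambda_1/\lambda_2,\quad S = \sqrt{\lambda_1^2+\lambda_2^2},$$

zeroed wherever λ₂ ≥ 0 (R_B is defined as 0 at λ₂ = 0, where S → 0
already kills the response). Parameters:

* **scales** {0.375, 0.75, 1.125, 1.5} mm — bracketing half the width of
  sub-millimetre to ~3 mm structures; the response peaks near σ ≈
  (ridge sd)·√2 under γ = 1, which the scale-selection test verifies.
* **β = 0.5** — the customary blobness weight; circular cross-sections
  of through-plane spaces still respond (≈ 0.6 on the phantom) because
  rasterised 2-pixel disks are never perfectly isotropic.
* **c** — adaptive: half the maximum γ-normalised Hessian Frobenius norm
  over the slice, shared across the *whole scale set*. One shared c is a
  deliberate choice: normalising each scale by its own maximum would
  divide out the γ-weighted amplitude ordering between scales, making
  the per-pixel argmax collapse to the first scale and destroying scale
  selection. A fixed numeric c can be supplied instead and is then used
  verbatim. A relative floor (10⁻¹⁰ of the intensity range) treats
  machine-epsilon Hessian residue on flat slices as zero response.

## 4. From vesselness to metrics

The map is thresholded at **t = 0.25** inside the ROI. This default was
calibrated once, on five noisy calibration phantoms spanning 10–40
structures, to the package's stated accuracy goals: component volume
unbiased (±8%), count within ±2, and ≥ 80% voxel coverage of a noiseless
reference tube. Lower thresholds admit the flanks of the larger-scale
responses and inflate volume by 60–90% at default noise. The threshold,
like every quantification parameter, is recorded in the provenance block
of each `vrs_metrics` object.

Components are labelled with 26-connectivity in 3D by default, so one
anatomical space crossing adjacent slices counts once; a per-slice
8-connected mode (`connectivity = "2d8"`) exists because 2D filtering
makes per-slice counting equally defensible, and it reports at least as
many regions. Components below 2 voxels are removed as noise.
Count = number of surviving components; volume = labelled voxels × voxel
volume (2.25 mm³ at the acquisition geometry); WM and brain volumes pass
through from the segmentation.

## 5. The cohort generator

Each seizure group draws its four linked variables — seizure duration
(min), course from onset to scan (days), VRs count, VRs volume — through
a **Gaussian copula**: a latent 4-variate normal with the group's
correlation matrix, mapped through truncated-normal margins whose parent
parameters are moment-matched so the *truncated* law has the configured
mean and SD. This construction was chosen over scale-shift-then-reject
because joint rejection sampling couples the margins: truncating
duration preferentially discards correlated low counts, biasing the
count mean by ~2% and attenuating r = 0.778 to ~0.72. With the copula,
margins are exact by construction and the latent correlations survive
the mild truncation within ~0.01.

Defaults encode the reference cohort: groups of 30 / 40 / 35; durations
7.16 ± 1.23 truncated to (5, 15] and 2.70 ± 0.45 truncated to (0.5, 5]
(the 5-minute group boundary and the 15-minute febrile-seizure
definition); course 9.40–9.60 ± ~1.4 days on (0, 15]; counts
642.70 ± 100.62 / 445.80 ± 66.10 / 430.77 ± 182.55; volumes
8514.63 ± 835.33 / 6390.43 ± 692.74 / 6048.37 ± 111.50 mm³ (the control
SD is used exactly as printed although it is an outlier against the
others — it is configurable); white-matter, brain-volume, head
circumference, age (6–60 months), gestational age (≥ 37 weeks) margins
per group; male proportions 70 / 73.3 / 74.3% (the printed percentages,
whose companion counts are internally inconsistent).

Two correlation pairs are unreported and must be completed before a
4 × 4 matrix exists. Zero-filling is *infeasible* for the long-seizure
group — with duration ⊥ course, 0.778² + 0.812² > 1 forces a negative
eigenvalue — and projecting to the nearest PSD matrix would perturb the
four published entries away from their recovery tolerances. The
defaults therefore complete duration–course at −0.5 (longer seizures
tend to be scanned sooner in these data) and count–volume at +0.85 (more
spaces mean more total volume); both group matrices are then positive
definite with the published entries kept exact. Both values are
arguments; if a user-supplied target set is still non-PSD a
Higham-style repair runs, and the generator refuses with the offending
pair named when repair must move a specified entry by more than 0.1.

One margin is worth flagging: age 28.07 ± 15.12 on (6, 60] is not
exactly realisable by any truncated normal (the family's maximum SD at
that mean on that interval is ≈ 14.9). The matcher always solves the
mean exactly (monotone 1-D root in μ) and takes the nearest feasible SD;
all margin means recover within 0.6% at n = 20 000.

## 6. Statistics

**Mann–Whitney U.** U counts pairwise wins with ties half-counted and is
reported as min(U, n₁n₂ − U). The p-value is exact from the null
distribution of U when n₁ + n₂ ≤ 16 and the pooled sample is tie-free
(beyond that the exact distribution buys nothing at desk scale), else a
normal approximation with tie-corrected variance and 0.5 continuity
correction. Against full enumeration the approximation is within 0.011
over the whole n₁ = n₂ = 8 support — the continuity-corrected variant is
the closest of the standard forms. Under a global null at the default
group sizes, the family-wise false-positive rate at the .017 level is
≈ 0.04 over 2000 replicates.

**Bonferroni.** The family-wise α = .05 is divided by m = 3 — the three
pairwise group comparisons — rendering as .017; the number of metrics is
deliberately not folded into m, mirroring how the comparisons are
reported. p-values render to three decimals with a "<.001" floor.
Sex is compared by chi-square (a rank test on a binary variable is
ill-defined), noted in the report.

**Pearson.** Sample r with a two-sided p from the t transform on n − 2
degrees of freedom; affine-invariant, sign-contract tested, and checked
against an independent implementation.

**LOESS.** Local *linear* regression (degree 1, span 0.5 → ⌈0.5·n⌉
nearest neighbours, tricube weights, 200-point evaluation grid) —
authored in-package because the cutoff machinery needs exact control of
the grid and window policy; an exact-surface reference implementation
serves as the test oracle. An equidistant or degenerate window falls
back to a local mean with a warning. Span, degree, and the smoothed
metric are all configuration keys recorded in every report.

**Cutoff detection.** The changepoint is the interior grid point
maximising |second difference| of the fitted curve (outer 5% of the grid
excluded; flat curves, whose criterion falls below 10⁻⁹ of the data
scale, raise an error rather than return noise). On piecewise-linear
data with a continuously distributed x this recovers breakpoints in the
4–8 minute range within ±0.15 min (median over 50 seeds); at a 3-minute
breakpoint the short left arm is narrower than the window half-width and
the corner smears to ≈ +0.6 min.

**A known limitation, honestly measured.** On the *default pooled
cohort* the duration axis is strongly bimodal: the short-seizure cluster
effectively ends near 3.7 min and the long-seizure cluster begins just
above 5, because the groups' printed summary parameters place almost no
mass near the boundary. The smoothed duration–count curve then rises
across an empty gap, and the maximum-curvature criterion localises the
dense-cluster edge: the detected cutoff is ≈ 3.9 min (median round = 4
over 50 seeds), not the 5-minute boundary the groups were defined by.
This is a property of detecting a changepoint on data that were already
dichotomised — every criterion variant we examined (signed curvature on
either side, curvature at coarser lags, maximum slope) lands in the
3–4 minute transition region. Recovering a 5-minute cutoff requires
duration mass near 5 on both sides, which post-split group summaries
exclude by construction. The acceptance script reports the measured
value.

## 7. Problem sizes, determinism, interfaces

Desk-scale test sizes: default phantoms (160 × 160 × 24), 20-phantom
recovery suites, cohorts of 105, moment-recovery cohorts of 20 000 per
group, 200 replicates for headline significance, 50 for cutoff medians,
2000 for type-I calibration — the full suite runs in well under five
minutes on one CPU. Every stochastic stage takes its seed from one root
seed via named sub-streams (`derive_seed`), so stages re-run in
isolation reproduce a full run; phantoms are bit-identical under a fixed
config, and the CLI's `end-to-end` manifests (config hash, seeds, output
MD5s) are identical across reruns modulo timings. Images travel as
NIfTI-1 with an RAS+ affine built from the voxel spacing (float32,
lossless for integer-valued payloads); cohorts as strict-schema CSV
(unknown group labels, missing duration/course on seizure subjects,
or locale-formatted numbers are rejected with the offending column
named); configuration as YAML validated against the default tree with
unknown keys refused.
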