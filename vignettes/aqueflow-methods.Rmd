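---
title: "Quantifying ventricular morphology, aqueductal resistance and CSF stroke volumes: methods and design notes"
author: "aqueflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aqueflow methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqueflow)
```

# The three measurements

Cerebrospinal fluid (CSF) exchanges between the third and fourth ventricle
through the cerebral aqueduct, a channel roughly 1-2 mm wide. Three
quantities summarize the morphology and dynamics of this system, each
computed by one pipeline in this package:

**Ratio-Area** — the lateral-ventricle area divided by the whole-brain area
on the axial T1-like slice that maximizes the ratio. Normalizing by brain
area removes most of the head-size variation that makes raw ventricular
area hard to compare across people. The pipeline (i) bilinearly
interpolates the slice to a 0.1 × 0.1 mm² grid, (ii) derives an intensity
threshold, (iii) labels pixels inside two rough, scripted ROI polygons
(ventricles; whole brain), and (iv) counts dark (label 0) pixels in the
ventricular ROI as Area-vent and bright (label 1) pixels in the brain ROI
as Area-brain, both excluding the choroid plexus and scaled by the pixel
area.

**Aqueductal resistance** — the hydraulic resistance of the aqueduct under
a laminar, quasi-steady (Poiseuille) flow model. The morphological volume
is maximum-intensity projected, interpolated to 0.03 × 0.03 mm², and
binarized with a threshold read off the intensity profile of a line drawn
across the narrowest point (resistance scales with D⁻⁴, so the narrowest
section must be segmented as faithfully as possible). A centerline is
extracted between two user landmarks, divided into `nSegments = 100`
equal-arc-length microchannels, and each microchannel contributes

$$R_i = \frac{128\,\mu\,L_i}{\pi\,D_i^4} \quad [\mathrm{mPa\,s/mm^3}],$$

with $L_i$ the segment length (mm), $D_i$ the lumen chord at the segment
midpoint normal to the centerline (mm), and $\mu = 0.71$ mPa s the dynamic
viscosity of water at 36 °C. Because the distal aqueduct widens into the
fourth ventricle and contributes almost nothing to the total resistance,
the reported endpoint is standardized at the first segment where
cumulative resistance reaches 95% of the total ("effective length"); the
effective resistance, effective length, and the mean/minimum diameter over
the effective length are reported.

**Ratio-SV** — the CSF stroke volume at the aqueduct (SV-aq) divided by
the stroke volume in the spinal canal at C2–C3 (SV-cv). Each site's cine
phase-contrast series (32 frames over an averaged cardiac cycle) is
de-aliased, segmented into a fixed CSF ROI from the velocity dynamics,
background-corrected against surrounding static tissue, and converted to a
flow-rate curve (ROI area × mean velocity). SV⁺ and SV⁻ are the periodic
trapezoid integrals of the positive and negative parts of the curve and
SV = (SV⁺ + SV⁻)/2. Because both sites beat with the same heart, their
ratio cancels heart-rate-driven variability; a guard rejects subjects
whose two series disagree in cycle duration by more than 10%.

A cohort layer reproduces the accompanying statistical protocol: mean ± SD,
Q1–Q3 (linear interpolation between order statistics, the convention of
`quantile(type = 7)`), CV% = SD/mean·100, a single-pass 3×IQR exclusion on
the three core parameters (Ratio-Area, Ratio-SV, resistance) with
quartiles computed before any exclusion, Wilcoxon rank-sum sex comparisons
with effect size $r = Z/\sqrt{n}$, and Spearman correlation matrices.

# Phantoms: what they emulate, and what they do not

No real MRI data ships with the package; every pipeline is validated on
synthetic phantoms whose ground truth is known in closed form.

* `generateTubeVolume()` sweeps a circle of diameter $D(s)$ along a
  straight or circular-arc planar centerline. A voxel is lumen iff its
  center lies inside the swept surface — deterministic and directly
  comparable to the analytic volume $\int \pi D^2/4\,ds$ and the analytic
  resistance $128\mu/\pi \int D^{-4} ds$, both carried in the ground-truth
  record.
* `generateBrainSlice()` builds an elliptical bright brain with two dark
  ventricle ellipses and an optional bright plexus disc; ventricle size
  peaks at a designated slice so the maximal-ratio slice is known by
  construction.
* `generateCineSeries()` fills a circular lumen with the parabolic profile
  $v(r,t) = 2\bar v(t)(1-(r/R)^2)$, adds a constant background phase
  offset, optionally wraps values into $(-\mathrm{VENC}, +\mathrm{VENC}]$
  (single wrap), and adds Gaussian noise. The ground-truth stroke volume
  is the dense quadrature of $S\,\bar v(t)$.
* `generateCohortTable()` draws per-sex parameter vectors from multivariate
  normals at the scale of a healthy-adult cohort, with ratio columns
  derived from their components and optional outlier injections.

What the phantoms deliberately do **not** model: k-space acquisition,
coil sensitivities, partial-volume intensities (membership is binary by
voxel center), physiologic noise beyond additive Gaussian, respiratory
modulation, and non-planar aqueduct geometry. Passing tests therefore
demonstrate that the *measurement chain* is unbiased and convergent on
geometry it can resolve — not that segmentation would survive the contrast
and artifact structure of clinical images.

# Numerical choices and tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `muMPaS` | 0.71 | mPa s | viscosity of water at body temperature |
| `nSegments` | 100 | — | microchannel count; equal arc length makes $L_i$ well defined |
| `endpointFraction` | 0.95 | — | cumulative-resistance cutoff standardizing the distal endpoint |
| `targetSpacingMm` (aqueduct) | 0.03 | mm | analysis grid for projection, mask and chords |
| morphometry target spacing | 0.1 | mm | analysis grid for area counting |
| `kAmp` | 3 | — | ROI amplitude criterion vs the background waveform |
| `cMin` | 0.5 | — | minimum waveform correlation with the seed pixel |
| `sdCapCms` / `magFloorFrac` | 1.0 / 0.2 | cm/s, — | static-tissue definition for background correction |
| `outlierK` | 3 | — | IQR multiplier of the screening rule |
| `mismatchLimitPct` | 10 | % | cardiac-cycle-mismatch QC limit |

Choices worth spelling out:

* **Threshold at a gradient plateau.** A sharp edge resampled bilinearly is
  an exactly linear ramp, so the "maximum gradient" is attained on a
  plateau spanning the whole edge. The threshold is taken at the middle of
  the plateau containing the first maximum, which lands on the edge
  midpoint (half-maximum intensity for a two-level edge); separated equal
  maxima still resolve to the first along the line.
* **Plexus operationalization.** With rough scripted ROIs, "bright pixels
  inside the ventricular ROI" would sweep up ordinary brain tissue, so the
  plexus is identified as bright connected components *wholly contained*
  in the ventricular ROI; the brain always crosses the ROI border. For a
  tight hand-drawn ROI the two definitions coincide.
* **Centerline.** Zhang–Suen thinning of the lumen mask, shortest skeleton
  path (8-connected, igraph) between the projections of the start/end
  landmarks, endpoints re-attached, 5-sample moving-average smoothing,
  uniform arc-length resampling. Deterministic and standard; no learned
  components.
* **Diameters as chords.** $D_i$ is the full chord of the mask along the
  normal to the smoothed centerline, with the mask sampled bilinearly and
  the boundary located at the 0.5 crossing (sub-pixel). A distance-
  transform radius was rejected because chords remain faithful under
  bends.
* **Order of flow corrections.** De-aliasing runs before ROI segmentation:
  the temporal unwrap needs no ROI, and correlation against a wrapped seed
  waveform would reject genuinely flowing pixels. Background correction
  then uses static tissue in a ring around the ROI.
* **ROI amplitude floor.** The amplitude criterion compares each pixel's
  peak-to-peak velocity with the amplitude of the *spatially averaged*
  background waveform (noise cancels in the average). An amplitude floor
  taken from single-pixel noise would clip the slow lumen rim and bias
  stroke volumes low by up to 20% at low velocities; the correlation
  criterion is the discriminative one.
* **Exclusion order.** Imaging failure → cycle-mismatch QC → 3×IQR
  screening, in one pass with pre-exclusion quartiles. The order matters:
  a QC-rejected subject never contaminates the screening quartiles.
* **Effect-size denominator.** $r = Z/\sqrt{n}$ uses the number of
  analyzed subjects. For the reference cohort (34 analyzed of 36 enrolled)
  only $\sqrt{34}$ reproduces the published effect sizes, although the
  source table's footnote names $n = 36$; the package follows the
  arithmetic that reproduces the printed values.

# Resolution, quantization and degenerate geometry

Voxel-center membership quantizes every edge by up to half a voxel per
side. Through $D^{-4}$ this is the dominant error of the resistance
pipeline: at the 0.35 mm reconstruction typical of morphological
acquisitions the diameter of a 2 mm tube can be off by ±10%, i.e. ±40% in
resistance — which is precisely why the workflow interpolates to 0.03 mm
and why the validation phantoms are generated on that grid, where the
recovered resistance lands within ~2% of the closed form. Refining the
analysis grid below the acquisition grid does *not* help by itself: the
edge position is frozen at acquisition, and the convergence ladder in the
tests (7.6% → 4.1% → 2.0% error at 0.12 → 0.06 → 0.03 mm) refines both
together.

Two degenerate configurations are avoided on purpose in defaults and
tests, and are worth knowing about when building new phantoms:

* an ellipse (or circle) whose center and semi-axes are exactly aligned
  with the pixel grid has its boundary pass through pixel centers, giving
  a systematic area bias (~4% for a 10 × 4 mm ventricle at 1 mm spacing)
  instead of the near-zero-mean quantization of generic placement;
* a perfectly straight, axis-aligned tube repeats the same edge phase in
  every cross-section, so diameter quantization never averages out along
  the lumen. A gentle bend (or any off-axis pose) restores error
  averaging; the diameter-scaling tests use 20° bends for this reason.

# Statistical approximations

The Wilcoxon implementation follows the classical normal approximation:
midranks, tie-corrected variance, continuity correction, two-sided p from
$Z$. Exhaustive enumeration of every rank configuration at group sizes
3–6 shows the approximation stays within 0.038 of the exact two-sided p
everywhere, within 0.02 once both groups have ≥ 5 members, and within
0.02 for 89% of all configurations; the worst cases sit at mid-range p
values irrelevant to significance calls. Spearman p values use the
two-sided t approximation on $n-2$ degrees of freedom; its type-I rate at
n = 34 is indistinguishable from nominal in the test suite's simulation.

CV% is undefined (reported missing) for non-positive means. When a
screened parameter has IQR = 0, the 3×IQR bounds collapse to [Q1, Q3] and
any value off the common one is excluded — the documented boundary
semantics.

# Problem sizes used in validation

The test suite and the acceptance script size their simulations to run on
a laptop-class single core: tube phantoms of ~10⁷ voxels at 0.03 mm for
the resistance recoveries, single- to five-slice brain stacks at 1 mm
(≈ 1.8 × 10⁶ interpolated pixels per slice), 49–67 px² cine series with 32
frames, cohorts of 34–36 subjects (up to 2000 for law-of-large-numbers
checks), 600–1000 replicate draws for type-I-rate and power checks. These
sizes were chosen so every stochastic check has comfortable Monte-Carlo
margins.

# Worked example

```{r example, eval = FALSE}
vol <- generateTubeVolume(tubePhantomSpec(
  lengthMm = 15, diameterMm = 2, voxelSpacingMm = 0.03))
prof <- analyzeAqueduct(vol, groundTruth(vol)$landmarks, resistanceParams())
summarizeAqueduct(prof)
#   resistance_mPa_s_mm3 user_length_mm effective_length_mm d_mean_mm d_min_mm
# 1             25.25510             15               14.25      2.01     2.01
```

The closed-form total for this cylinder is $128 \cdot 0.71 \cdot 15 /
(\pi \cdot 2^4) = 27.12$; the pipeline recovers the total within 2% and
reports the 95% effective resistance (25.26) over the effective length
14.25 mm = 0.95 × 15 mm, with the diameter recovered to within one
analysis pixel.

# Known limitations

* The resistance model is quasi-steady Poiseuille in a 2D projection:
  no pulsatile (Womersley) correction, no full 3D tubular segmentation,
  no computational fluid dynamics.
* One axial slice stands in for ventricular volumetry by design.
* The de-aliasing handles single wraps only; waveforms beyond 2×VENC are
  rejected at generation and flagged at analysis.
* Phantom validation bounds algorithmic error, not acquisition artifacts;
  thresholds (`kAmp`, `cMin`, static-tissue caps) are stand-ins for
  operator-tuned values and are all surfaced in `flowParams()` and
  `runConfig()`.
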