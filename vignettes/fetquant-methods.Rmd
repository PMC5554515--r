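---
title: "Methods: phantom design and agreement statistics in fetquant"
author: "fetquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom design and agreement statistics in fetquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetquant)
```

## The problem

Amino-acid PET (FET) of brain tumors is quantified almost entirely through
ratios and volumes: a background mean B from a "banana"-shaped ROI in
healthy contralateral tissue, tumor mean and maximum uptake relative to it
(T~MEAN~/B, T~MAX~/B), and the biological tumor volume (BTV) enclosed by
the isocontour at 1.6 × B. On hybrid PET/MRI systems the attenuation map
must be derived from MR instead of CT, and the residual attenuation-
correction (AC) error propagates into each of these quantities — not
uniformly, but with spatial structure: a global underestimation, a radial
gradient between the brain surface (near mis-modeled bone) and its center,
focal warps where tissue classes are misassigned, and voids near metal
implants.

`fetquant` implements the quantification chain and the agreement
statistics needed to evaluate an MR-based AC method against a CT
reference, and couples them to a synthetic phantom cohort generator whose
bias fields reproduce exactly that error structure. Because no clinical
images are distributed with the package, every analysis can be exercised
end to end on phantoms where the injected error is known.

## Phantom model

A scene is an ellipsoidal brain (semi-axes 0.32/0.38/0.30 of the grid
extent) of uniform background uptake (arbitrary SUV-like units; every
downstream metric is a ratio or a volume, so absolute normalization
cancels), containing:

* spherical tumor foci at a contrast multiplier over background
  (cohort draws: radius 11–18 mm, contrast 2.2–4.0), each with a
  parabolic "hot core" rising `focus_peaking` (default 0.15) above the
  rim value — giving T~MAX~ a well-defined, noise-robust peak location,
  as used for biopsy targeting;
* an *infiltrative margin* of moderately elevated uptake
  (1.35–1.5 × background, 6–12 mm wide) around each focus. Under correct
  AC it stays below the 1.6 × B isocontour; under a local overestimation
  it can be pulled above threshold as a thick blob. This is the substrate
  for the nodular BTV warps observed clinically — a hard-edged sphere
  alone cannot produce them;
* optional resection cavity and extratumoral hot structures
  (skin/vascular analogs) outside the brain, covered by the exclusion
  mask;
* a background ROI placed automatically as a curved slab in the
  hemisphere contralateral to the first focus, above the mid-axial
  plane, at least 15 mm from every focus surface, trimmed to
  `roi_volume_ml` (default 15 mL). The clinical placement is manual and
  not algorithmically specified anywhere, so these placement rules are
  fixed, documented parameters. The same ROI is used for every AC method
  of a study.

The sharp truth volume defines the ground-truth tumor mask (focus voxels
above 1.6 × background; phantoms below the 1 mL inclusion floor are
rejected). The *imaged* volume `pet_truth` is the truth blurred with a
5 mm FWHM Gaussian (`psf_fwhm_mm`), emulating reconstruction resolution
and post-filtering. This blur is essential: with a hard-edged tumor,
any threshold between 1.6 and the tumor contrast yields the same mask and
the BTV would be artificially immune to AC bias.

### Bias fields

AC error is modeled as a strictly positive multiplicative field applied
post hoc to `pet_truth`, not by simulating attenuation physics and
reconstruction: the clinical characterization of AC error *is* a
spatially structured multiplicative under/over-estimation of activity,
and the post-hoc model keeps the pipeline desk-scale. Inside the brain

field = `global_scale` × (1 + g(depth)) × Π nodules × Π voids,

where depth is the Euclidean distance to the brain edge normalized to
[0, 1] over brain voxels and g interpolates linearly from
`gradient_surface` to `gradient_center` (only the existence of a
surface-to-center gradient is documented, so linear-in-depth is the
simplest faithful choice). Nodules are Gaussian bumps; voids are uniform
spherical depressions. Outside the brain the field equals
`global_scale`. With all parameters at identity the field is exactly 1.

Noise is i.i.d. relative Gaussian (`output = truth × field × (1 + ε)`),
applied after the resolution blur; the default `noise_sd = 0.03`
represents post-filtered image noise. Poisson/reconstruction noise is out
of scope; i.i.d. noise slightly overstates voxel-to-voxel independence,
which mainly affects the stability of the arg-max (peak location) — one
reason the default is below raw-count noise levels.

### Cohort profiles

Per-method bias distributions are truncated normals with the truncation
at the reported maximum error magnitude, reproducing published
mean ± SD (max) triplets of the T~MEAN~ relative error: DIXON
−14.9 ± 5.2 % (max 29.3 %), UTE −7.2 ± 3.1 % (max 16.9 %), RESOLUTE
−1.9 ± 1.9 % (max 7.6 %). The truncation is applied symmetrically (the
literature states the maximum in the underestimation direction only).
Gradients (DIXON −6 %/+4 % surface/center, UTE −3 %/+2 %, RESOLUTE none)
and nodular warp rates (37 %, 11 %, 0 %) follow the documented
phenomenology; nodule amplitudes (0.40 and 0.32, FWHM 25/20 mm, aimed at
the infiltrative margin) were chosen so that triggered warps actually
exceed the 1 mL clinical relevance bound after smoothing — weaker bumps
produce only thin caps that the shape-deviation discriminator correctly
suppresses. Vendor methods get a 4 % rate of implant-like posterior
voids. A drawn geometry that cannot host the background ROI on a small
grid is redrawn inside the seeded stream, like a screening exclusion, so
cohorts keep their size and reproducibility.

Follow-up examinations reuse the subject's bias model at both timepoints
(repeat attenuation maps of the same subject are near-identical in
practice) with freshly drawn noise; ground-truth BTV and T~MAX~/B changes
are drawn from truncated normals (±40 % / ±20 % caps).

## Delineation and spatial metrics

`delineate_btv()` thresholds strictly above `threshold_ratio × B`
(default 1.6; "above" is read as strict, so exact ties are excluded),
removes the exclusion mask, and keeps 26-connected components that
intersect a prior mask (the clinician-seed analog, used by the pipeline)
or, without a prior, components of at least `min_component_ml`
(default 0.1 mL). An empty result is a valid delineation flagged
`empty = TRUE`, not an exception. The T~MAX~ peak is the
lexicographically smallest voxel index among maxima — a deterministic
tie-break. Voxel indices are 1-based (R convention); world coordinates
use the voxel-center convention `origin + (index − 1) × spacing`, so all
distances are in mm regardless of indexing base.

`shape_deviation()` separates clinically meaningful focal warps from
uniform one-voxel contour shifts: the signed mask difference is smoothed
(FWHM 5 mm, matching the reconstruction post-filter) and binarized at
|0.5|; surviving 26-connected components are reported with volumes, and
warps are components above 1 mL. A one-voxel rim never reaches the 0.5
level after 5 mm smoothing; an attached 8 mm bump does — both properties
are asserted in the test suite against flood-fill oracles. Both
parameters are configurable because no reference values are published.

Peak shifts of exactly 10 mm count as exceeding the biopsy criterion
("< 10 mm" passes).

## Agreement statistics

All paired comparisons are analyzed on the log scale, d = ln(test/ref),
consistent with log-normally distributed ratio metrics, and exponentiated
back to percentages:

* mean difference: 100·(e^d̄ − 1), with 95 % CI
  100·(e^{d̄ ± 1.96·SD_d/√n} − 1);
* 95 % limits of agreement: 100·(e^{d̄ ± 1.96·SD_d} − 1);
* 95 % CI of each limit (default): LoA_log ± 1.96·√3·SD_d/√n on the log
  scale — the standard large-sample variance of an agreement limit. A
  `literal` variant, 100·(e^{d̄ ± 3·SD_d/√(2n)} − 1), is selectable for
  sensitivity analyses because the printed source formulas for both CI
  expressions are typographically ambiguous; the package treats the
  standard readings as defaults and keeps the alternative inspectable
  rather than silently choosing.

When subjects contribute repeated studies (follow-ups), SD_d comes from a
one-way variance-components decomposition: with k subjects, m_i studies
each, within- and between-subject mean squares MS_W and MS_B, and
m₀ = (N − Σm_i²/N)/(k − 1), the between-subject variance is
max(0, (MS_B − MS_W)/m₀) and SD_d = √(σ_b² + MS_W). Negative component
estimates are truncated at zero. With one study per subject this reduces
exactly to the ordinary sample SD (asserted in the tests, alongside a
cross-check of the mean squares against `stats::aov`). `n` in the CI
denominators counts studies; the subject count is reported alongside,
since the correction does not resolve which the original analyses used.

Acceptance of a study under a test AC method uses the clinical
absolute-OR-relative rule, strict as printed: |ΔT~MEAN~/B| < 0.05 or
< 5 %, |ΔT~MAX~/B| < 0.1 or < 5 %, |ΔBTV| < 2 mL or < 10 % (reference
denominator). T~MAX~/B categories use the cut-offs 2.0 (reactive) and
2.4 (active); the boundary values themselves are assigned to the
equivocal class, an explicit, testable reading of "in-between".

Follow-up changes use the baseline value of the stated pairing as the
percent denominator (matching the convention of the published worked
numbers), a ±2 % "stable" band (an artifact parameter; the clinical
reports use direction words without defining a band), and deviation
criteria of 5 percentage points for ratio metrics and 10 for the BTV.
Percentages are kept at full precision and rounded to integers only at
presentation.

## Numerical choices

* Connectivity is 26-neighborhood throughout (the clinical software's
  convention is unspecified); components and the distance transform are
  small Rcpp kernels (BFS labeling; Felzenszwalb's exact separable
  squared-distance transform with anisotropic spacing; separable
  Gaussian smoothing truncated at 4σ with zero padding). Each is verified
  against an independent brute-force R implementation in the tests.
* Depth normalization maps the shallowest brain voxel to 0 and the
  deepest to 1, so gradient endpoints are attained exactly.
* Strictly positive bias fields are enforced; a nonpositive field aborts
  generation. Negative noisy voxels are clipped to zero with a reported
  count.
* Determinism: every stochastic step derives from an integer seed; RNG
  state is saved and restored around seeded sections, so library calls
  do not perturb the caller's stream. Identical configuration and seed
  give bit-identical cohorts, tables and files.

## Problem sizes

The phantom default is a 128³ grid at 2 mm isotropic spacing — comparable
to clinical PET reconstruction resolution — and the packaged acceptance
script analyzes a 51-subject cohort (14 with follow-up, 65 studies, four
AC methods) at that size. The test suite exercises the same code paths on
24³–96³ grids and 200-case random-oracle batteries, sizes chosen so the
full suite completes in a few minutes on one CPU.

## What passing tests do and do not show

The generator reproduces the *structure* of AC error (global, gradient,
nodular, void), the published per-method error magnitudes as injected
distributions, and the clinical metric definitions. It does not simulate
attenuation physics, reconstruction, registration error, anatomical
variability, tumor heterogeneity beyond the parabolic core, or
correlated noise. Tests passing on phantoms therefore validate the
*analysis chain* — delineation, metrics, statistics, follow-up logic —
and the qualitative method ordering, not the clinical performance of any
AC method on real data. Cohort-level magnitudes (failure fractions,
Jaccard means, LoA widths) emerge from the simulation and track the
published ordering (DIXON worst, RESOLUTE best) without being fitted to
the published values.
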