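# fetquant

Quantitative agreement analysis of PET attenuation-correction (AC)
methods for amino-acid (FET) brain-tumor imaging.

## The problem

On PET/MRI, the attenuation map must be derived from MR instead of a CT,
and residual AC error propagates into the semi-quantitative metrics that
drive clinical reading of FET-PET: the background mean **B** (a curved
ROI in healthy contralateral tissue), the tumor-to-background ratios
**T<sub>MEAN</sub>/B** and **T<sub>MAX</sub>/B**, the **biological tumor
volume** (BTV) enclosed by the isocontour at 1.6 × B, and the location of
the T<sub>MAX</sub> peak used for biopsy targeting. `fetquant` is for
imaging physicists and methods researchers who need to quantify, per
patient and per cohort, whether an MR-based AC method reproduces the
CT-based reference well enough for these metrics to be clinically
interchangeable.

The package provides:

* **Phantom cohorts** (`phantom_spec()`, `generate_phantom()`,
  `generate_cohort()`): seedable 3D brain phantoms with tumor foci,
  infiltrative margins, resection cavities, extratumoral hot structures,
  and per-method multiplicative bias fields with the spatial structure of
  real AC error — global scaling, a radial surface-to-center gradient,
  focal nodular warps, metal-implant voids (`bias_field_model()`,
  `make_bias_field()`, `apply_bias()`).
* **Delineation and spatial metrics** (`delineate_btv()`,
  `tumor_metrics()`, `jaccard()`, `peak_shift()`, `shape_deviation()`):
  adaptive isocontour segmentation at 1.6 × B with exclusion masks and
  26-connected component selection; Jaccard overlap; peak displacement
  against the 10 mm biopsy criterion; and a smoothed-difference analysis
  that distinguishes focal contour warps (> 1 mL) from uniform one-voxel
  shifts.
* **Agreement statistics** (`bland_altman()`,
  `sd_with_repeated_measures()`, `acceptance_check()`,
  `classify_category()`): Bland–Altman analysis of log ratios
  d = ln(test/ref), with mean difference 100·(e^d̄ − 1), 95 % CI
  100·(e^{d̄ ± 1.96·SD_d/√n} − 1), limits of agreement
  100·(e^{d̄ ± 1.96·SD_d} − 1), and a one-way variance-components SD when
  subjects contribute repeated examinations; clinical acceptance rules
  (|ΔT<sub>MEAN</sub>/B| < 0.05 or 5 %, |ΔT<sub>MAX</sub>/B| < 0.1 or
  5 %, |ΔBTV| < 2 mL or 10 %); T<sub>MAX</sub>/B categories (reactive
  < 2.0 < equivocal < 2.4 < active).
* **Longitudinal analysis** (`change_metrics()`, `compare_changes()`,
  `cross_modality_change()`): baseline→follow-up percent changes under
  same-method or mixed AC pairings, with deviation flags against the
  reference change.
* **Orchestration** (`analysis_config()`, `run_pipeline()`): one
  seeded configuration runs simulate → delineate → compare → tabulate,
  streaming study by study, with NIfTI/CSV/JSON input and output.

## Worked example

Simulate a small cohort under three MR-AC-like bias profiles against an
identity CT-AC analog, and summarize T<sub>MAX</sub>/B agreement:

```r
library(fetquant)

cfg <- analysis_config(n_subjects = 8, followup_fraction = 0.25, seed = 42,
                       grid_shape = c(64, 64, 64))
bundle <- run_pipeline(cfg)

bundle$agreement[bundle$agreement$metric_name == "t_max_over_b", ]
#>    method  n mean_pct ci_lo ci_hi loa_lo loa_hi
#>     DIXON 10     7.43  1.10  14.2  -11.4   30.2
#>  RESOLUTE 10     0.73 -0.58   2.1   -3.4    5.0
#>       UTE 10     1.57  0.63   2.5   -1.4    4.6

bundle$summary$failed_acceptance
#> $DIXON: 4   $RESOLUTE: 0   $UTE: 0     (of 10 studies)

bundle$summary$mean_jaccard
#> $DIXON: 0.842   $RESOLUTE: 0.923   $UTE: 0.922
```

Reading: across 10 studies (8 subjects, 2 with a follow-up pair, so the
repeated-measures SD correction is active), the DIXON-like profile
overestimates T<sub>MAX</sub>/B by 7.4 % on average with 95 % limits of
agreement from −11 % to +30 %, and 4 of 10 studies fail the clinical
acceptance rule; the RESOLUTE-like profile stays within ±5 % for
essentially all studies and fails none. The Jaccard means show the same
ordering for spatial overlap of the delineated BTV.

A single comparison prints as:

```r
bland_altman(subset(bundle$comparisons,
                    metric_name == "t_max_over_b" & method == "RESOLUTE"))
#> <bland_altman_result> t_max_over_b: n = 10 studies (8 subjects)
#>   mean % difference 0.73 (95% CI -0.58 to 2.06), p = 0.297
#>   95% limits of agreement -3.35 to 4.99
```

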