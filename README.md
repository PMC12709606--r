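# slscgcnr

Coherence-based ultrasound beamforming and gCNR classification of cystic
versus solid breast masses.

## The problem

Complicated cysts are benign, fluid-filled breast masses whose interiors
fill with acoustic clutter on conventional B-mode ultrasound, making them
look like hypoechoic solid masses and driving false-positive workups.
Short-lag spatial coherence (SLSC) imaging maps each pixel to the
correlation of backscattered echoes across the receive aperture instead of
their amplitude: diffuse tissue scattering stays coherent across nearby
elements while clutter inside a fluid cavity does not, so fluid interiors
appear dark on SLSC images even when B-mode shows them filled in.

The package is for imaging scientists and biostatisticians who want a
tested, reproducible implementation of that classification pipeline:

* a linear-array RF **channel-data simulator** (focused multi-element
  transmits, diffuse speckle, circular fluid/solid lesions, partially
  correlated clutter) standing in for non-public clinical raw data;
* **beamformers** for B-mode (delay-and-sum + envelope) and SLSC images;
* **lesion scoring**: equal-area, same-depth mass/tissue ROI pairs and the
  generalized contrast-to-noise ratio with threshold classification;
* **cohort accounting**: eligibility filters and statistical-subgroup
  selection over mass records;
* **reader statistics**: empirical ROC curves with trapezoidal AUC,
  percentile bootstrap CIs, lower-bound AUC for single operating points,
  DeLong's paired test, Fleiss' kappa with large-sample significance, and
  kappa difference tests;
* a **study orchestrator** (`run_study()`) that chains all of the above
  with per-stage seeds and a reproducibility manifest.

## The statistics at the core

For delay-aligned aperture signals `s_i(n)` at one pixel, the lag-`m`
spatial coherence is

    R(m) = (1/(N-m)) * sum_{i=1..N-m} [ sum_n s_i(n) s_{i+m}(n) ]
           / sqrt( sum_n s_i(n)^2 * sum_n s_{i+m}(n)^2 )

and the SLSC pixel value is `sum_{m=1..M} R(m)` with `M = 7` (10% of the
64-element aperture), negative values truncated, displayed on the full
linear scale. For a mass ROI and an equal-area tissue ROI at the same
depth,

    gCNR = 1 - OVL,   OVL = sum_b min( p_mass(b), p_tissue(b) )

over a shared histogram; a mass is called **fluid** when its gCNR is at or
above the threshold (default 0.76, acceptable range 0.62-0.85) and
**solid** otherwise. Diagnostic accuracy uses trapezoidal AUC (equal to
the tie-aware Mann-Whitney statistic), 1000-iteration percentile
bootstraps, `(sens + spec)/2` lower-bound AUCs for categorical reader
assessments, DeLong's test for paired AUC differences, and Fleiss' kappa
with the printed interpretation bands (0.21-0.40 fair, 0.41-0.60
moderate, 0.61-0.80 substantial, ...).

## Worked example

Image one cluttered fluid lesion through the physics pipeline and
classify it:

```r
library(slscgcnr)

les <- lesion_spec(center = c(0, 0.020), radius = 2.5e-3, content = "fluid",
                   clutter_level = 0.6)
res <- image_mass_gcnr(les, seed = 8)
sprintf("gcnr_bmode = %.3f, gcnr_slsc = %.3f", res$gcnr_bmode, res$gcnr_slsc)
#> "gcnr_bmode = 0.712, gcnr_slsc = 0.974"
classify_mass(res$gcnr_slsc)   # tau = 0.76
#> "fluid"
classify_mass(res$gcnr_bmode)
#> "solid"
```

The clutter fills the anechoic lesion on the B-mode image enough to drop
its gCNR below the 0.76 threshold (a false solid call), while the SLSC
image still separates the incoherent interior from tissue almost
perfectly — the mechanism the method exploits.

A full synthetic study (175 simulated records, eligibility filtering to
145, subgroup of 112 = 16 complicated cysts + 96 solid masses, six
readers, 1000 bootstrap iterations) runs in about a second:

```r
report <- run_study(study_config(mode = "statistics", seed = 11,
                                 output_dir = tempfile()))
#> [cohort] 175 records simulated
#> [filters] 145 eligible -> 112 analysis masses (16 positive, 96 negative)
report
#> <study_report> 175 masses (112 analysis subgroup); mean AUC slsc 0.962, bmode 0.834
#>   kappa: task1_bmode 0.36, task2_bmode_slsc 0.50, gcnr_slsc_0.76 0.68, gcnr_slsc_0.73 0.70
#>   outputs: ...
```

The mean AUC is the average of the six per-reader AUCs of gCNR scores over
the 112-mass subgroup; the kappa line reports inter-reader agreement for
the two reading tasks and for thresholded SLSC-gCNR calls at 0.76 and
0.73. CSV/JSON tables (ROC points, confusion counts, kappa table,
threshold trade-off, manifest with every seed) are written to
`output_dir`.

## Package layout

* `R/`, `src/` — implementation (R + Rcpp beamforming kernels)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/slsc-gcnr-methods.Rmd` — model assumptions, parameter
  defaults, generator design, numerical choices and limitations
* `inst/scripts/run_study.R` — command-line wrapper around `run_study()`
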