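---
title: "Coherence imaging and gCNR classification of cystic versus solid masses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence imaging and gCNR classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Complicated cysts — benign, fluid-filled breast masses containing debris —
often mimic hypoechoic solid masses on conventional B-mode ultrasound
because acoustic clutter fills their interiors with artifactual echoes.
Amplitude cannot separate the two, but spatial coherence can: diffuse
tissue scattering produces echoes that remain correlated across the
receive aperture, whereas clutter inside a fluid cavity does not. This
package implements the resulting classification pipeline end to end:
short-lag spatial coherence (SLSC) beamforming of raw channel data,
ROI-based scoring with the generalized contrast-to-noise ratio (gCNR),
threshold classification, and the multi-reader diagnostic-accuracy
statistics used to evaluate it — together with a synthetic channel-data,
cohort and reader-panel generator that stands in for the non-public
clinical data.

## Image formation

**Channel-data model.** `simulate_channel_data()` uses a single-scattering,
attenuation-free linear model. For every scan line a focused transmit is
synthesized from the full walking aperture: each transmit element
contributes a Gaussian-windowed tone (default 1.5 periods of the 8 MHz
center frequency) delayed so that all contributions align at the focal
depth. Each receive element then records the spherically spread (`1/r`)
echo of that field from every scatterer. The multi-element transmit is
essential rather than cosmetic: the lateral amplitude profile of the
focused beam is what gives diffuse speckle its predicted receive-aperture
coherence (see below). At the transmit focus, each element's envelope
peaks at its geometric round-trip time to within half an RF sample, which
is the package's delay oracle.

**Clutter.** The cited clinical work does not characterize the clutter
statistics of complicated cysts, so the clutter model is this package's
own construct, with one principle taken from the physics: purely
element-independent noise would be trivially removed by coherence imaging
*and* suppressed by a factor of sqrt(N) under delay-and-sum, so it can
neither fool SLSC nor fill a lesion on B-mode. Clutter is therefore
injected at the channel level inside the lesion's round-trip depth gate
as a mixture of

* an element-correlated component: a shared band-limited trace written
  onto each element pre-delayed by that element's receive path for the
  lesion depth, so that dynamic receive focusing sums it near-coherently
  (it fills the lesion on B-mode) while its lag-domain coherence remains
  well below that of focused speckle; and
* an element-independent band-limited component.

`correlated_fraction` (default 0.5) sets the power split. `clutter_level`
scales the mixture relative to the RMS of the line's speckle signal.

**Beamforming.** `apply_receive_delays()` performs standard dynamic
receive focusing with linear interpolation between RF samples on a depth
grid at the RF rate (`dz = c / (2 fs)`). `das_bmode()` sums across the
aperture with uniform apodization and detects the envelope as the
magnitude of the axial analytic signal. `slsc_image()` computes, per
pixel, the normalized correlation

R(m) = (1/(N-m)) * sum_i [ sum_n s_i(n) s_{i+m}(n) ] /
        sqrt( sum_n s_i(n)^2 * sum_n s_{i+m}(n)^2 )

over an axial kernel centered at the pixel, and maps the pixel to
`sum_{m=1..M} R(m)`. Element pairs with zero energy are skipped with the
averaging denominator reduced; an all-zero pixel yields 0.

**Parameters and defaults.**

| parameter | default | rationale |
|---|---|---|
| `n_elements` | 64 | active receive aperture of a linear breast probe |
| `pitch` | 0.3 mm | L8-17-class array |
| `center_freq` / `sampling_freq` | 8 / 40 MHz | RF sampling at 5 samples per period |
| `transmit_focus_depth` | 20 mm | typical breast lesion depth (reported mean 11 mm, masses below 5 mm excluded) |
| `M` | 7 | 10% of the 64-element receive aperture |
| `kernel_samples` | one wavelength (11 RF samples) | standard axial kernel in the coherence-imaging literature; the source study does not state its kernel |
| `truncate_negative` | post-sum | the "full linear scale after truncating negatives" display; whether the clinical prototype truncated per lag or post-sum is not stated, so both are implemented and post-sum is the default |
| apodization | uniform | unstated in the source; uniform is the common default |
| receive aperture | fixed 64 elements | aperture growth (constant f-number) is unstated; fixed is the default |

## gCNR scoring and classification

`gcnr()` estimates `1 - OVL`, the complement of the overlap of the two
ROIs' pixel-value histograms, on a shared binning spanning the pooled
range (256 bins by default; the estimator is the package's choice, as the
source names only the statistic). It is computed on linear-scale pixel
values — B-mode envelope or SLSC sums — never on display-compressed
images; up to discretization it is invariant under strictly increasing
transforms, which the tests verify against log compression. If both ROIs
are constant and identical the value is 0 (a single shared bin).

`auto_tissue_roi()` translates the mass mask laterally by its width plus
a margin, preferring the side with more room, so the tissue ROI has the
same size and depth band as the mass ROI. `classify_mass()` calls a mass
fluid when its gCNR is at or above the threshold (default 0.76, within
the acceptable range 0.62–0.85). A value exactly at the threshold is
classified fluid; the printed worked examples only constrain the strict
cases (0.75 versus 0.76 classifies solid), so the tie rule is the
package's choice.

In the beamformed pipeline each mass has one deterministic ROI, so the
per-mass gCNR comes from a single "reader". Where multiple views of a
mass are scored, the package scores them independently and defaults to
their mean, since how the clinical study combined radial/antiradial views
into a per-mass value is unstated.

## Cohort and reader-panel generator

`simulate_cohort()` reproduces the study accounting exactly: 175
enrolled records of which 30 carry exclusion reasons (hyperechoic 2,
unknown content 16, incomplete follow-up 2, no screenshots 2, superficial
4, outside the field of view 4), leaving 145 eligible masses — 16
complicated cysts, 96 solid (71 benign, 25 malignant), 11 simple cysts,
22 mixed — of which 112 enter the statistical subgroup. Exclusion
reasons are record attributes set by the generator; the filters implement
the accounting, not pixel-level diagnosis.

For statistics-only analyses each mass receives a latent gCNR per imaging
arm drawn from a truncated normal whose category means/SDs are free
generator parameters. The defaults were chosen once so that the synthetic
cohort emulates the clinically reported separations — binormal AUC near
0.96 for SLSC-gCNR and near 0.80 for B-mode-gCNR, with per-reader ROI
jitter (SD 0.12) producing moderate agreement of thresholded calls — and
were not revisited afterwards. Reader panels draw content ratings
(solid / fluid / mixed / uncertain) from a truth-conditioned categorical
model; `agreement_coupling` is the probability that a reader copies a
shared latent rating, which tunes Fleiss' kappa continuously from chance
to perfect agreement.

The beamformed cohort (`simulate_imaging_cohort()`) replaces score
sampling with physics: fluid lesions are anechoic with clutter level
drawn from U(0.3, 0.9); solid lesions have echogenicity U(0.15, 0.7) —
the low end produces the very hypoechoic solids that mimic cysts on
B-mode — and no clutter. Phantoms are 14 x 10 mm speckle bands around
the 20 mm focus with 35 scatterers/mm^2, imaged on 24 lines at 0.6 mm
spacing; gCNR uses 64 bins because the ROIs hold one to two hundred
pixels. These problem sizes keep a 112-mass cohort at roughly a minute of
CPU while preserving the mechanism under test.

**What the generator does and does not emulate.** It reproduces speckle
statistics (Rayleigh envelope after depth-gain normalization), the van
Cittert–Zernike coherence of diffuse scattering, clutter-degraded B-mode
contrast in fluid masses, and the printed cohort accounting. It does not
model nonlinear propagation, frequency-dependent attenuation, element
directivity, heterogeneous tissue layers, reader fatigue or
case-difficulty correlations. Passing tests therefore demonstrate that
the implementation reproduces the method's mechanism under its stated
assumptions, not that the clinical effect sizes would be reproduced on
real data; the clinical headline numbers depend on the non-deposited
images and ROIs and are emulated only statistically.

## Statistics

* **ROC/AUC** — thresholds sweep all observed scores plus 0 and 1 (the
  exact empirical ROC rather than a fixed lattice); a mass is called
  fluid when its score is at or above the threshold; AUC is the
  trapezoidal integral and equals the tie-aware Mann–Whitney statistic,
  which the tests verify exhaustively at small n.
* **Bootstrap CIs** — percentile intervals (not BCa, matching the plain
  description of the source methods) from 1000 joint resamples of
  (score, label) pairs; single-class resamples are redrawn and counted.
  The mean AUC across readers resamples masses jointly to preserve
  inter-reader correlation.
* **Lower-bound AUC** — `(sens + spec)/2`, the area of the two-segment
  ROC through a single operating point; used for categorical reader
  assessments, with reader-resampling bootstrap CIs for the panel mean.
* **DeLong's test** — paired placement-value comparison of correlated
  AUCs with a two-sided normal approximation. How a binary reading was
  compared against a continuous score in the source is not described;
  this package treats binary calls as two-valued scores and documents
  that choice. Zero-variance differences are flagged and reported at
  p < 1e-16.
* **Fleiss' kappa** — `(Pbar - Pe)/(1 - Pe)` over the rating categories,
  with the large-sample null variance. Both the corrected
  Fleiss–Nee–Landis estimator (default) and the original 1971 form are
  implemented because the source's references admit either. Agreement is
  assessed over all rated masses. A single-category panel makes the
  chance correction undefined; it is reported as kappa 1 with a
  degeneracy flag. Kappa differences use a two-sided z with variances
  added under an independence approximation (no covariance is defined
  for paired panels in the source); the output flags the approximation.
* Two-sided tests at alpha = 0.05 throughout; no multiple-testing
  correction is applied, matching the source analysis.

## Numerical choices

* Seeds: every stochastic operation is a pure function of its inputs and
  an integer seed; `run_study()` derives per-stage seeds from the master
  seed by hashing the stage name modulo 2^31 - 1, so stages can be
  re-run in isolation and a manifest records every seed.
* Alignment uses linear interpolation between RF samples; out-of-range
  reads are zero with a warning when pixels fall outside the recorded
  window.
* The Rayleigh check normalizes the envelope by a smoothed depth-gain
  curve (the analogue of scanner time-gain compensation) before testing,
  because fixed-focus imaging makes speckle energy depth-dependent.
* The coherence triangle `1 - m/N` is asserted in a band around the
  transmit focus; away from it, fixed-focus defocus legitimately narrows
  coherence, as it does on real systems.
* Degenerate inputs: all-zero images cannot be log-compressed; all-zero
  coherence kernels yield 0; constant identical ROIs yield gCNR 0;
  single-class label vectors are rejected by the ROC and DeLong routines.

## Problem sizes used by the checks

The test suite beamforms one 27 x 12 mm speckle phantom (82 lines, about
10^4 image pixels) for the coherence and envelope statistics, ten
112-mass beamformed cohorts for the SLSC-versus-B-mode direction, and one
hundred statistics-only cohorts for bootstrap-coverage of the closed-form
binormal AUC. These sizes were chosen as the smallest that leave the
statistical assertions comfortable margins.

## Known limitations

* The channel-data model omits attenuation, element directivity and
  multiple scattering; absolute gCNR values in the beamformed pipeline
  are therefore not calibrated to clinical ones, and comparisons between
  arms (SLSC versus B-mode) are the meaningful outputs.
* The clutter construct has two free parameters (level and correlated
  fraction) that real cysts do not announce; conclusions that depend on
  the exact clutter spectrum are out of reach.
* Histogram-based gCNR is biased upward for small ROIs with many bins;
  the pipeline mitigates this with 64 bins but does not correct it.
* The kappa difference test ignores the positive covariance between
  panels rating the same masses and is therefore conservative.
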