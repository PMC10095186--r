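---
title: "Viability gating for imaging flow cytometry: model, calibration and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viability gating for imaging flow cytometry: model, calibration and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifcgate)
```

## The measurement model

Imaging flow cytometry records, for every acquired object, a brightfield
image and per-channel fluorescence images alongside the integrated
intensities. With RedoxSensor Green (RSG) reporting reductase activity and
propidium iodide (PI) reporting membrane damage, a dual-stained bacterial
sample separates into four physiological groups on the RSG×PI plane:
active (RSG-high, PI-low), dead (RSG-low, PI-high), and two double-positive
mid-active groups distinguished by their RSG level (higher for mid-active
II). The mid-active groups grow poorly or not at all after sorting, which
is why they are the natural candidates for the viable-but-nonculturable
(VBNC) state and why plate counts alone under-describe a stressed
preparation.

Raw event streams also contain objects that must not enter this
interpretation: out-of-focus acquisitions, non-cellular debris (matrix and
carrier particles, fragmented cells), and multi-cell aggregates. `ifcgate`
follows the standard three-step cleanup before quadrant assignment:

1. **Focus gate.** Brightfield Gradient RMS — the RMS of the
   central-difference gradient magnitude over the object mask, normalized
   by mean masked intensity — is low for blurred objects. Events below
   `gradient_rms_min` are labelled `out_of_focus`.
2. **Singles gate.** Mask area outside `[area_min_um2, area_max_um2]` or
   aspect ratio (minor/major, 1 = round) below `aspect_ratio_min` indicates
   aggregates (large, elongated) or sub-cellular fragments (small).
3. **Classifier gate.** A Fisher linear discriminant trained on two small
   "truth" populations (exemplar cells vs exemplar debris) scores every
   remaining event; scores at or below zero are debris.

Surviving events are assigned by quadrants on log10 intensities:
RSG > `t_rsg` and PI ≤ `t_pi` is active; RSG ≤ `t_rsg` and PI > `t_pi` is
dead; double-positives split at `t_mid` into mid-active I/II;
double-negatives remain `unclassified`. Every event therefore carries
exactly one of eight labels, and with the default all-events denominator
the eight percentages sum to 100.

## Why percentages are reported against all events

Published subpopulation tables for these preparations do not sum to 100%
(the control *E. faecium* composition, for example, totals ≈ 90.8% across
the four groups). That is consistent with percentages taken over all
acquired events, with debris and other unclassifiable objects making up
the remainder — so `summarize_subpopulations()` defaults to the
`all_events` denominator, and the synthetic generator assigns any
unallocated mixture fraction to debris. The `gated_cells` denominator is
available for sensitivity analysis.

## The synthetic generator

The generator is the package's test bed: it produces events whose ground
truth is known, with the statistical structure the analysis assumes.

**Fluorescence.** Each class draws (RSG, PI) from a bivariate log-normal;
see `default_intensity_params()` for the log10-RFU centers, spreads and
correlations. No published numeric centers exist for these distributions,
so the defaults are a documented calibration choice fixed once: classes
are placed 6 or more within-class SDs apart along their discriminating
axis, matching the clean visual separation of published scatter plots.
Debris is intentionally *not* well separated in fluorescence: its broad
distribution (log10 SD 0.5) leaks into the positive quadrants, the way
stained fragments and autofluorescent carrier particles do. This is what
makes the classifier gate consequential — removing it measurably
contaminates the subpopulation counts, a property the test suite asserts.

**Morphology and features.** Cell length/width come from `shape_spec()`
(default: a slightly elongated coccobacillus, 1.3 × 0.8 µm, the typical
LAB morphology). Aggregates contain `2 + Poisson(1)` member cells and sum
their members' intensities and areas; defocused events are cells with a
degraded Gradient RMS. The generator emits feature columns at two levels:

* *table level* — per-event feature values drawn from label-conditional
  distributions (`default_feature_params()`), used for large-n gating
  studies;
* *image level* — `render_event_image()` draws the actual three-channel
  pixel data (ellipse silhouettes, mask-proportional fluorescence,
  Gaussian defocus blur), and the features module recomputes the features
  from pixels.

The image path is validated against the table path on small n (intensity
recovery within ±5%, channel ordering by label, blur monotonicity of
Gradient RMS), while the 20,000-event benchmarks run on the table path.
This two-level design keeps the statistical benchmark honest — features
enter the gates exactly as the feature module defines them — while keeping
the image renderer a first-class, tested component rather than a fixture.

Debris texture differs from cells in co-occurrence statistics (higher
entropy, larger directional spread), reflecting irregular, grainy objects
versus smooth cell interiors; those are the features the classifier
weights most heavily.

**What the generator does not emulate.** Real spectral spillover between
the RSG and PI detectors (single-laser dual-dye designs typically forgo
compensation), instrument-specific point-spread functions (blur is
Gaussian), autofluorescence spectra, day effects, and staining-efficiency
drift. A pipeline that passes the synthetic benchmarks is therefore
demonstrated to be *internally correct* (it recovers known ground truth
under the stated model), not validated against instrument data.

## Threshold calibration

Quadrant thresholds default to the valley (minimum-density point) of the
pooled log10 intensity densities, searched inside fixed windows:
`t_pi` in log10 RFU [1.4, 2.2], `t_rsg` in [1.2, 1.8], and `t_mid` in
[2.3, 2.85] among double-positive events. The windows encode the dye
chemistry's coarse geometry (where the positive/negative boundary can
plausibly lie) and make valley-finding robust when one mode is rare — with
a 0.8% subpopulation, an unconstrained valley search would wander.
Calibration happens after debris removal, on the events that reach
quadrant assignment; subsets smaller than 50 events keep the configured
threshold. Intensities are floored at `pseudo_count` (default 0.1 RFU)
before the log transform. The focus threshold is fixed by default
(0.2, about 4 within-class SDs below the in-focus mode) and can instead be
calibrated by Otsu's method when a defocused mode is present — Otsu on a
unimodal histogram would split the cells themselves, so this is opt-in.

## The classifier

`train_classifier()` z-scores the candidate features by training mean/SD,
computes the Fisher direction `w = Sw⁻¹(m₁ − m₀)` from the pooled
within-class covariance (ridge-regularized with a warning if singular),
keeps the `k = 7` features with largest |weight|, refits on those, and
sets the offset so the midpoint of the standardized class means scores
exactly 0. The positive class ("cell") orientation is explicit metadata;
flipping it negates all weights, so a model whose weights print negative
is the same classifier viewed from the debris side. Scores within 1e-9 of
zero are treated as ties and left unclassified. Feature selection by
|standardized weight| (rather than stepwise search) keeps training
deterministic. On Gaussian two-class data of Mahalanobis separation Δ the
held-out accuracy approaches Φ(Δ/2), which the suite checks at Δ = 2.

## Plate counts and sorting

`simulate_plating()` draws colony counts as
Poisson(concentration × 10^exponent × volume) per plate of a decimal
dilution series (an `efficiency` < 1 option emulates plate-count
underestimation). `plate_count_estimate()` implements the 30–300 rule:
only plates with 30–300 colonies qualify; each qualifying plate yields
`count / (10^exponent × volume)` and qualifying plates are averaged
(plain mean by default; a colony-weighted mean — pooled colonies over
pooled effective volume — is available and is slightly less biased,
because conditioning a low-dilution plate on reaching 30 colonies
truncates its Poisson distribution from below). When no plate qualifies
the no-estimate flag is returned rather than a number. At 2.7 × 10⁸
cfu/mL the plain-mean estimator recovers the configured concentration to
within ≈3% over 200 simulated series.

`simulate_sorting()` sorts `n_cells = 24` cells per subpopulation and
medium; each grows with its subpopulation's probability, and growing
wells follow a logistic OD600 trajectory after a 10 h + exponential(20 h)
lag. The lag spread is chosen so a realistic minority of wells cross the
detection threshold only between the 48 h and 72 h reads — growth counts
at 72 h are never below those at 48 h, and the growth-percentage grid is
exactly `round(100·k/24, 1)` (75% = 18/24, 83.3% = 20/24, 20.8% = 5/24).
OD600 readings include the sterile-broth blank, which
`growth_percentages()` subtracts before applying the 0.1 threshold.

## Numerical conventions

* **GLCM.** 32 gray levels by default (equal-width bins over the masked
  range), symmetric matrices, four directions at offset `granularity`,
  within-mask pixel pairs only; entropy in bits; the per-direction spread
  is the sample SD. A constant patch gives entropy 0, homogeneity 1.
* **Axes.** Axis length is `4·√eigenvalue` of the (population) second
  central moments — the full axis of the equivalent ellipse; aspect ratio
  is minor/major. A 1/12-pixel variance floor keeps single-pixel-wide
  masks finite.
* **Sentinels.** Undefined features (empty mask, mask too small for the
  co-occurrence offset, zero intensity sum) are `NA`; gates exclude such
  events from further stages and they end as `unclassified`, so one bad
  segmentation never aborts a batch.
* **Determinism.** All generators take explicit seeds and restore the
  caller's RNG state; identical inputs give byte-identical tables.
* **File formats.** CSV (full schema, canonical) and a minimal FCS 3.0
  codec (float32 list mode, numeric columns only) for interoperability
  with cytometry software. Proprietary IFC containers are out of scope.
* **Mask/channel naming.** Instrument-style mask and channel codes are
  mapped to the package's named channels (`bf`, `rsg`, `pi`) and two mask
  methods (`otsu_threshold`, `morphology_combined`); texture features are
  computed on the brightfield threshold mask and the morphology-combined
  fluorescence mask respectively. This mapping is a documented
  interpretation of vendor conventions, not a claim of equivalence.

## Problem sizes

The shipped benchmarks use 20,000 events per composition (50,000 for the
sub-1% active case, where the rare class needs more events for a stable
percentage), 32-event truth populations, 200 dilution series for the
plating estimator, and 100-image batches for the render/feature loop
checks. These sizes put binomial sampling error well inside the tolerances
being asserted (a 62.9% fraction at n = 20,000 has SE ≈ 0.34 points) while
keeping the full suite fast.

## Known limitations

Beyond the generator's idealizations listed above: quadrant gating assumes
the four groups are separable by two straight log-intensity boundaries
plus one split; strongly overlapping or drifting populations would need
model-based clustering instead. The classifier is linear by construction —
that is the point of reproducing the weighted-feature design — and will
underperform on debris classes that are not linearly separable in the
chosen features. Aggregate handling stops at flagging; member-cell
decomposition is not attempted.
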