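---
title: "Vessel-centric quantification of blood-spinal-cord-barrier leakage"
author: "cordleak"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-centric quantification of blood-spinal-cord-barrier leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordleak)
```

## The measurement model

Hemoglobin is normally confined to the vascular lumen; finding it in the
cord parenchyma, distributed radially around vessels, is the readout of
blood-spinal-cord-barrier (BSCB) compromise used throughout this package.
Every quantity is defined on a multichannel section raster with a known
pixel size (µm/px), so that all mask radii, areas and densities are
physical. The pipeline composes a small number of primitives:

* a **robust background-relative threshold**: within a region, pixels not
  in the top intensity decile are declared background and a pixel is
  signal if it exceeds `median(bg) + k * mad(bg)`. The top-decile exclusion
  keeps bright objects from inflating the background estimate; the
  median/MAD pair makes the rule reproducible where a vendor
  implementation would not be.
* an **adaptive threshold** (local mean + `k` local SD over a square
  window) for leakage patches, insensitive to smooth intensity gradients
  across a section.
* **binary morphology with disc structuring elements** (dilate, erode,
  fill holes) from which the vessel-compartment masks are assembled:
  perivascular = `dilate(lectin, 10 µm) \ erode(fill(lectin), 5 µm)`,
  glia limitans = `dilate(lectin, 20 µm) \ fill(lectin)`. On an ideal disk
  vessel of radius 10 µm these reproduce the closed-form annulus areas
  π(20² − 5²) and π(30² − 10²) within 5 % discretisation error, which the
  test suite asserts.

## Tunable parameters and their defaults

All criteria live in one `quant_config()` object.

| parameter | default | units | rationale |
|---|---|---|---|
| vessel area window | 10–10 000 | µm² | brackets capillary-to-venule cross-sections; the source protocol used unstated criteria |
| vessel / object intensity `k` | 3 | MADs | conventional robust outlier cut |
| Hb proximity radius (gray matter) | 25 | µm | "a defined radius" is never published; results must be reported with the value used |
| adaptive window | 200 | µm | far larger than any vessel caliber, smaller than leakage patches |
| leakage-mask `k` | 2 | SDs | see below |
| leakage patch gate | 300 | µm² | separates patches from isolated lumen signal |
| inclusion gate | 8 | µm equivalent diameter | selects neuronal over glial inclusions |
| soma area window | 150–3000 | µm² | alpha-motor-neuron somata (15–60 µm diameter) |
| edge margin | 100 (real slides) / 0 (synthetic) | µm | tissue edges show elevated nonspecific labelling; synthetic sections have no edge artifact |
| ELISA LOD | 6.25 | ng/mL | assay limit of detection |
| Grubbs α | 0.2 | – | deliberately permissive one-pass screen |

Two defaults deserve explanation because they were genuinely open design
choices:

* **Leakage-mask `k` = 2 with a 300 µm² patch gate and hole filling.** The
  leakage mask must separate extravasation patches from intravascular
  signal, because every vessel lumen also exceeds its local background.
  With an exponentially decaying halo, a `k` of 3 truncates the detected
  patch to a thin annulus that falls below any patch-size gate for
  capillary-caliber vessels; `k = 2` keeps the detected patch well above
  the gate while the gate still removes isolated lumens. Holes are filled
  so that a vessel enclosed by its own halo lies *inside* the patch, which
  is what the centroid classification rule requires. The generic
  `adaptive_threshold()` keeps `k = 3` as its default.
* **Centroid classification rule.** A vessel is leaked iff its centroid is
  inside the leakage mask — the most literal reading of a vessel "located
  within" a leakage area. An overlap-fraction rule is provided
  (`leak_rule = "overlap"`) for sensitivity analyses.

Two further choices are worth recording: integrated-intensity scores are
**background-subtracted** by default (the background median from the
threshold step), so that a leak-free section scores ≈ 0 — a testable zero —
with a raw-sum mode available (`background_subtract = FALSE`); and
per-vessel annulus pixels are attributed to their **nearest vessel**
(Voronoi propagation of vessel labels) when annuli of neighbouring vessels
touch, since per-vessel averaging is otherwise ill-defined.

## What the synthetic generator emulates

`generate_section()` renders: an elliptical tissue boundary with a
two-lobed ("butterfly") gray matter and labelled anterior horns; lectin
rings of uniformly drawn lumen radius (3–8 µm); intravascular hemoglobin in
every lumen; an exponential radial halo `A · exp(−(d − r)/λ)` (default
rim amplitude 150, λ = 15 µm) around the leaked subset
(`round(leak_fraction · n)` vessels); SMI-32 somata confined to the horns;
pTDP-43 puncta with diameters straddling the 8 µm gate (the ground truth
records both the nominal and the as-rasterised equivalent diameter);
optionally a perivascular NVU marker whose measured intensity around leaked
vessels is scaled by a configurable factor; and Poisson shot noise plus
Gaussian read noise over a uniform tissue autofluorescence background
(default SNR ≈ 10 at the halo rim). Vessel centres keep a minimum
separation of 40 µm, a typical CNS inter-capillary distance. All
randomness in a section flows from one seed, recorded in the cohort
manifest; identical specs produce bit-identical rasters.

The generator does **not** emulate: optical point-spread blur, stitching
seams, flat-field inhomogeneity, fixation-dependent edge artifacts,
anatomically faithful horn shapes, vessels cut obliquely (all
cross-sections are circular), or spatially correlated background. Passing
recovery tests on these images therefore demonstrates the correctness of
the measurement chain — thresholds, morphology, component logic,
normalization, statistics — not robustness to every artifact of real
slide-scanner data. The halo shape and amplitude are free parameters of the
generator, not estimates of tissue values.

The CSF arm (`generate_csf_cohort()`) draws hemoglobin and total protein
from log-normal distributions; the default location/scale parameters are
chosen so the arms reproduce the reported cohort medians and upper
quartiles (control 39.86 / 310.4 ng/mL, ALS 74.25 / 889.8 ng/mL), and
values below the 6.25 ng/mL LOD are censored at the LOD with a flag —
preserving the rank statistics the Mann–Whitney comparison uses, without
inventing sub-LOD values.

## Statistics

Between-subject two-way ANOVAs use sum-to-zero contrasts and Type III sums
of squares, matching mainstream biostatistics software on unbalanced
layouts such as 4 controls vs 13 ALS cases by 3 cord levels. The Sidák
family (`1 − (1 − p)^m`) covers the group contrast at each cord level
(m = 3); the Tukey family covers the three levels within each group via the
studentized range; comparisons across levels within one cohort alone use a
one-way ANOVA with Tukey post-test; leaked vs non-leaked comparisons use a
repeated-measures two-way ANOVA (both factors within case) with
Sidák-adjusted paired contrasts. The Mann–Whitney test enumerates the exact
U distribution when the smaller sample has ≤ 8 observations and there are
no ties, and otherwise uses the tie-corrected normal approximation; the
test suite verifies exact agreement with exhaustive enumeration for all
partitions of n₁ + n₂ ≤ 10. Grubbs' screen is single-pass and two-sided:
`G = max|x − x̄|/s` against the t-based critical value; deviation ties break
to the first index; zero variance flags nothing. The exclusion, when it
fires on a control case, is persistent: the case leaves every subsequent
table, reproducing the n = 5 → 4 control bookkeeping.

## Numerical choices and degenerate inputs

* µm→px conversion rounds half away from zero with a 1 px floor, so a
  nonzero physical radius never produces an empty structuring element.
* The adaptive threshold subtracts its local mean with a small relative
  guard (10⁻⁶) because FFT-based convolution leaves ~10⁻¹³ jitter on flat
  regions that would otherwise randomly litter the mask.
* Constant rasters threshold to an empty mask with a warning; a vessel with
  no qualifying marker pixel records a missing intensity (never zero); an
  inclusion load with zero motor neurons is missing (never infinite);
  components touching diagonally merge (8-connectivity, union-find on top
  of EBImage's 4-connected labelling).
* Coordinates are 1-based `(row, col)` matrices throughout, as is idiomatic
  in R; bounding boxes are closed ranges.
* TIFF float pages are stored rescaled to \[0, 1\] with the scale factor in
  the JSON sidecar, because TIFF float storage outside that range is
  undefined in the writer used.

## Problem sizes used by the simulation studies

The recovery and calibration studies run on 160 × 160 px sections at
2.5 µm/px (0.4 mm fields) with 18 vessels, three cord levels, one section
per case and level, 3 control + 5 ALS cases, and 50 simulation seeds per
study; classification accuracy uses ten noise-free 192 × 192 px sections.
These sizes were chosen so a full study completes in minutes on one CPU
while keeping every per-cohort test (4–8 cases per cell) in the regime the
cohort statistics are designed for. The injected effects mirror the study
design: a 2× thoracic halo amplitude for the level-patterning study and a
7.4 % perivascular marker deficit for the leaked-vessel comparison.

## Known limitations

* Touching inclusions are not split (no watershed); counts are of
  8-connected objects after thresholding.
* Touching vessels merge into one record; the per-vessel annulus partition
  resolves shared annulus pixels but not merged lumens.
* The proximity radius, vessel criteria and leakage-mask parameters are
  unpublished in the source protocol; all results depend on the configured
  values and should be reported with them.
* The white-matter score deliberately counts all qualifying hemoglobin
  objects (no proximity condition), so intravascular signal contributes a
  baseline; comparisons across groups and levels are unaffected because the
  baseline is common, but absolute scores are not pure extravasation.
* Below-LOD CSF values are censored at the LOD; analyses other than rank
  tests should treat the censoring flag explicitly.
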