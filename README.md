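# cordleak

Quantification of blood–spinal-cord-barrier (BSCB) leakage in multichannel
fluorescence sections of human spinal cord, with a synthetic ground-truth
generator that makes every stage of the analysis testable end to end.

## The problem

In ALS, plasma and erythrocyte components such as hemoglobin escape across a
compromised BSCB into the cord parenchyma. Post-mortem studies quantify this
leakage from slide-scanned sections co-stained for hemoglobin, a vessel
lectin (*Ulex europaeus* agglutinin), nuclei, and one additional marker
(SMI-32 for motor neurons, pTDP-43 for inclusion pathology, or a
neurovascular-unit protein such as collagen IV or GFAP). The quantification
is vessel-centric:

- **Vessel detection.** The lectin channel is thresholded relative to
  background; 8-connected components passing size criteria (default
  10–10 000 µm²) become vessel records, assigned to gray or white matter by
  centroid and counted per mm² (vessel density).
- **Hemoglobin scoring.** Extravascular hemoglobin objects are segmented
  relative to background and scored as background-subtracted integrated
  intensity per mm² of compartment. In gray matter an object only counts if
  it lies within a proximity radius (default 25 µm) of a detected vessel; in
  white matter, where vessels are scant, the proximity condition is dropped.
- **Leaked vs non-leaked vessels.** An adaptive threshold (local mean +
  *k*·SD over a 200 µm window) segments leakage patches in the hemoglobin
  channel; a vessel is *leaked* if its centroid falls inside a patch.
  Vessel-compartment masks — vascular, perivascular
  (`dilate(lectin, 10 µm) \ erode(fill(lectin), 5 µm)`), and glia limitans
  (`dilate(lectin, 20 µm) \ fill(lectin)`) — then let marker intensity be
  averaged per vessel and compared between leaked and non-leaked vessels.
- **Neuropathology.** SMI-32-positive motor-neuron somata are counted in the
  anterior horns and normalized to horn area; pTDP-43 inclusions are counted
  with an equivalent-diameter gate (`2·sqrt(area/π) ≥ 8 µm`, which selects
  neuronal over glial inclusions) and normalized per motor neuron.
- **CSF biomarker.** ELISA plate absorbances are converted to hemoglobin
  concentrations through a four-parameter logistic standard curve
  `A(x) = d + (a−d)/(1+(x/c)^b)`, with duplicate averaging, a 1:10 dilution
  factor, censoring at the 6.25 ng/mL limit of detection, and per-sample
  normalization to total protein.
- **Cohort statistics.** Sections are averaged to case × level values
  (mean of 3 sections); a one-pass Grubbs screen (α = 0.2) may exclude one
  control case; the battery then runs Mann–Whitney, Welch *t*, two-way
  group × level ANOVA (Type III) with Sidák (group at each level) and Tukey
  (levels within group) post-tests, repeated-measures two-way ANOVA for
  leaked vs non-leaked comparisons, and Pearson/linear regression.

Because the original image data are not publicly deposited, the package
ships a synthetic-section generator (`generate_section()`,
`generate_cohort()`, `generate_csf_cohort()`) that renders cord geometry,
vessel rings, exponential leakage halos, somata, puncta and
Poisson–Gaussian noise with full ground truth, so every claim above is
backed by parameter-recovery tests.

## Worked example

```r
library(cordleak)

sec <- generate_section(section_spec(seed = 1),
                        case = "A01", level = "thoracic", section = 1L)
res <- quantify_section(sec$image, sec$truth$regions)
t(round(res[, c("wm_hb", "gm_vessel_density", "neuron_density",
                "inclusion_load", "leaked_vessel_count")], 2))
#> wm_hb               1563897.59
#> gm_vessel_density       203.97
#> neuron_density          481.06
#> inclusion_load            0.40
#> leaked_vessel_count       8.00
sum(sec$truth$vessels$leaked)   # ground truth: 8 of 25 vessels leak
#> [1] 8
```

`wm_hb` is the integrated extravascular hemoglobin intensity per mm² of
white matter; vessel and neuron densities are per mm²; `inclusion_load` is
pTDP-43 inclusions per motor neuron; the classifier found exactly the 8
leaked vessels the generator rendered.

The bundled donor table reproduces the published cohort demographics:

```r
donor_summary()
#>     group  n age_mean age_sd pmd_mean pmd_sd n_female n_male
#> 2 control  5     87.4   5.41     17.1   9.34        3      2
#> 1     ALS 13     61.8  12.19     21.2  12.50        8      5
```

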