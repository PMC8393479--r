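Package: cordleak
Title: Quantification of Blood-Spinal-Cord-Barrier Leakage in Fluorescence
    Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vessel-centric quantification of blood-spinal-cord-barrier (BSCB)
    leakage from multichannel fluorescence sections of spinal cord. Detects
    lectin-positive vessels, builds vascular, perivascular and glia-limitans
    annulus masks, scores extravascular hemoglobin per tissue compartment with
    an optional vessel-proximity condition, classifies vessels as leaked or
    non-leaked against an adaptive-threshold leakage mask, counts SMI-32
    motor neurons and size-gated pTDP-43 inclusions, converts ELISA plate
    readings to CSF hemoglobin concentrations through a four-parameter
    logistic standard curve, and runs the cohort statistics (Mann-Whitney,
    Welch t, two-way ANOVA with Sidak or Tukey post-tests, Grubbs outlier
    exclusion). A synthetic-section generator with known ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    minpack.lm,
    car,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
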