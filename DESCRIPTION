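Package: silamdyn
Title: Proteome Dynamics from Pulsed Stable-Isotope Labeling and Spectral Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pulsed stable-isotope labeling in mammals (SILAM, Lys(6))
    proteomics data quantified by spectral counting. Classifies peptide-spectrum
    matches by isotope label and trypsin terminal specificity, estimates
    newly-synthesized proteome and peptidome fractions per vascular layer,
    computes per-protein condition ratios with regulation and exclusive-synthesis
    calls, scores protein turnover from non-tryptic peptide evidence with
    endogenous cleavage-site mapping, and calls disease-specific phosphosites.
    Includes a synthetic post-search PSM data generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
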