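Package: aldhgate
Title: ALDH-Activity Based Discrimination of Normal and Leukemic Stem
    Cells in AML Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated gating and classification pipeline for paired
    (native/DEAB-inhibited) Aldefluor flow-cytometry samples of acute
    myeloid leukemia (AML) bone marrow.  Gates lymphocytes, CD45dim
    blasts and CD34/CD38 stem and progenitor compartments, derives the
    ALDH positivity threshold from the DEAB-treated control aliquot,
    segregates ALDH-bright from ALDH-low events, computes
    lymphocyte-standardized mean fluorescence intensities, scatter
    ratios, and HSC versus LSC calls, and classifies samples as
    CD34-positive or CD34-negative AML.  Includes a synthetic event
    generator with known ground truth, cohort summary tables with
    median rows, and readers for FCS 3.0/3.1 and delimited-text event
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
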