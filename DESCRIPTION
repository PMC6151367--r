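Package: phantomrad
Title: Digital PET Phantoms and Radiomic Feature Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates seeded three-dimensional digital PET phantoms with
    irregular, heterogeneous lesions of known ground truth (volume,
    sphericity, uptake heterogeneity), emulates acquisition and
    reconstruction effects in the image domain, segments the metabolic
    tumor volume with fixed and adaptive threshold methods, extracts 58
    morphological, histogram and texture (GLCM, GLRLM, GLSZM, NGTDM)
    radiomic features, and runs a stability, reproducibility and
    significance battery (Friedman, COV stability classes, intraclass
    correlation, Mann-Whitney, correlation with ground-truth
    heterogeneity) over simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
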