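Package: vesselquant
Title: Compartment-Resolved Quantification of Tumour Angiogenesis on Brightfield IHC Virtual Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring relative endothelial area (REA) in
    compartment-labelled regions of CD34/DAB-stained breast-cancer sections.
    Assembles camera tiles into virtual slides with flat-field shading
    compensation and overlap-based registration, separates Hematoxylin from
    CD34-DAB by reference-shade optical-density unmixing, extracts
    DAB-positive endothelial area inside 1-mm circular regions of interest
    tagged as tumour-associated stroma, tumour parenchyma or invasive front,
    and computes the cohort statistics layer (pooled REA, group means,
    compartment ratios, Pearson correlations with exact two-tailed
    significance, paired t-tests). Includes a synthetic slide-phantom and
    patient-cohort generator with known ground truth so the whole pipeline
    is testable without patient material.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
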