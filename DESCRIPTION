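Package: ciliascreen
Title: Hit Calling, Quality Control and Phenotype Quantification for
    High-Content Ciliogenesis Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plate-level statistics and multi-tier hit calling for
    high-content imaging screens of primary cilia, as used in drug and
    siRNA screens of ciliogenesis modulators. Implements robust z-scores
    against pooled plate controls, strictly standardised mean difference
    (SSMD) screen quality metrics, per-batch normalised hit cutoffs with
    cytotoxicity exclusion, replicate concordance and plate QC gates, and
    the bespoke phenotype quantifications of such screens (z-stack basal
    body docking classification, Gabor filter-bank scoring of acto-myosin
    fibre textures, SMO ciliary occupancy, dual-luciferase normalisation,
    organoid cyst staging and ellipse tubule morphometry). A seeded
    generative simulator of 96-well screen datasets with planted effects
    supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
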