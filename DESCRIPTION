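Package: wheatphen
Title: Canopy Phenology, Multi-Environment Trial Statistics and Heterosis
    for Hybrid Wheat Phenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hybrid wheat field phenomics. Models
    canopy NDVI dynamics in thermal time with a three-phase
    (linear-linear-logistic) development model to extract stay-green
    statistics (TFN90/50/10/1) and phase areas; computes adjusted genotype
    means (BLUEs) and broad-sense heritability from multi-location augmented
    designs; quantifies per-hybrid mid-parent and best-parent heterosis with
    per-trait summaries; and tests trait associations (grain protein
    deviation, thousand-kernel-weight versus grain number, heading-date
    adjusted senescence). Includes a synthetic field-trial generator that
    emulates an incomplete factorial crossing scheme grown in an augmented
    design over several locations, for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
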