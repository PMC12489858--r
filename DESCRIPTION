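Package: pathprs
Title: Pathway-Specific Polygenic Risk Scores and Structural Biomarker
    Associations in Age-Related Macular Degeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes global and pathway-specific polygenic risk scores
    (complement, ARMS2/HTRA1, extracellular matrix, lipid metabolism) for
    age-related macular degeneration from imputed genotype dosages, applies
    variant-level quality control including an exact Hardy-Weinberg
    equilibrium test, and fits multivariable linear models relating the
    scores to disease stage and intermediate-AMD structural biomarkers
    (reticular pseudodrusen, pigmentary abnormalities, hyper-reflective
    foci, iRORA/cRORA), with estimated-marginal-means stage contrasts. A
    seeded synthetic cohort generator with planted pathway effects supports
    end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    emmeans,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
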