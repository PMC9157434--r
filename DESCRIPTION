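Package: fpdscore
Title: Automated Footpad Dermatitis Scoring and Agreement Statistics for Poultry
Version: 1.0.0
Authors@R:
    person("fpdscore", "maintainers", email = "fpdscore@example.org", role = c("aut", "cre"))
Description: Image-based severity scoring of footpad dermatitis (FPD) in
    poultry feet photographed against a blue background: colour-based foot
    segmentation, metatarsal footpad localisation via the largest inscribed
    circle of the distance transform, lesion detection with two algorithm
    variants, and classification onto the five-level Hocking severity scale.
    Ships a seeded synthetic foot-image generator with full ground truth, a
    ground-truth detection audit (footpad, alteration, presentation angle),
    Krippendorff's alpha (nominal, ordinal, interval) with bootstrap
    confidence intervals, confusion-matrix performance measures with binomial
    standard errors, Landis-Koch interpretation bands, and a command-line
    interface binding the pieces into reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
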