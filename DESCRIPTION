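Package: shallowplan
Title: Predict Shotgun Metagenomic Library Composition from Two-Target qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plan shallow shotgun metagenomic sequencing from quantitative PCR
    data. Calibrates the difference between human beta-actin (ACTB) and
    bacterial 16S rRNA gene cycle thresholds against the observed percentage
    of microbial (non-human) reads using five regression families, including
    a logistic-growth model shipped with published constants; predicts
    library composition with one-tailed prediction bounds and validity
    flags; converts predictions into required total sequencing depth for a
    target number of microbial reads; and provides a seeded rarefaction
    engine computing richness, Shannon and Berger-Parker indices over a
    depth grid from taxonomic count profiles. Includes generators for
    synthetic calibration sets and taxonomic communities, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
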