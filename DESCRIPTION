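Package: zfscreen
Title: Hit Triage and Chemoinformatics for Zebrafish Whole-Organism Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for triaging whole-organism phenotypic drug screens scored
    by ordinal in situ hybridisation readouts, as used in zebrafish inner-ear
    and myelination screens. Per-embryo scores (0-3, three embryos per well)
    are aggregated into rescue categories, confirmed across retests, filtered
    by a counter screen, and resolved into mechanism classes by comparing
    rescue of hypomorphic versus strong mutant alleles. Compound libraries
    are structured chemically with ECFP4 (Morgan radius-2) fingerprints,
    Tanimoto similarity, Bemis-Murcko scaffolds, Ward clustering with polar
    layouts, and thresholded similarity networks. Includes SSMD effect sizes,
    LD50 dose-response fitting with profile-likelihood intervals, and a
    seeded synthetic-screen generator with planted scaffold families and
    activity classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
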