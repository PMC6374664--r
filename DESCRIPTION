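Package: driftdiet
Title: Metabarcoding Diet Analysis with Drift-Survey Prey Availability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 18S V9 metabarcoding diet studies of
    stream fish predators. Processes sequence count tables into per-sample
    prey proportions (quality screening, greedy OTU clustering at a fixed
    edit distance, reference-based assignment to ecologically significant
    units, rarefaction, predator self-read removal), quantifies
    amplification bias from mock tissue homogenates via relative
    correction factors, converts nightly drift-net counts to
    prey-availability biomass, and computes the dietary statistics:
    Schoener overlap between pooled predator diets with a paired
    sign-flip permutation test for seasonal change, and Manly/Chesson
    prey selectivity against drift-survey availability. Includes a
    seeded synthetic-community generator for end-to-end validation and
    the calibration tables of the motivating field study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
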