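Package: tadfuse
Title: Two-Condition Hi-C Comparison at Matrix, Compartment and TAD Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential analysis of chromosome conformation (Hi-C) contact
    maps between two cell states, built for desk-scale studies of chromatin
    reorganization such as the CLL-to-DLBCL (Richter) transformation. Provides
    ICE matrix balancing, distance-decay (P(s)) curves with crossover
    detection, A/B compartment eigenvectors with saddle plots and switch
    classification, insulation-score TAD calling with cross-condition
    TAD-fusion detection, and integration of differential-expression gene
    lists with boundary and merged-TAD annotations. A synthetic contact-map
    generator with planted compartments, TADs, fusions and switches makes
    every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
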