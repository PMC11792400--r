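Package: decomplex
Title: Decomposer-Exploiter Dynamics in Plant Residue Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the trophic division of labour between
    fungal decomposers and bacterial exploiters during plant residue
    decomposition. Implements a genome-level plant residue decomposition
    index (PDI) built from CAZyme family annotations, trophic-role
    classification rules, flux balance analysis (FBA) on small
    constraint-based metabolic models, and a community simulation
    framework with cross-feeding that tracks carbon utilization breadth,
    secretion efficiency, and growth-rate divergence across an uptake-flux
    ladder. Seeded synthetic-data generators emulate the statistical
    structure of real CAZyme profiles, metabolic networks, abundance
    tables, and homology hit tables so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
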