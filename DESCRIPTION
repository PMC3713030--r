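Package: coalhyb
Title: Coalescent Simulation Tests for Hybridization Versus Incomplete
    Lineage Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes hybridization from incomplete lineage sorting in
    multi-locus phylogenetic data by comparing tree-to-tree distances among
    posterior samples of gene trees against null distributions generated by
    neutral coalescence simulated within each observed gene tree.  Implements
    the phi test statistic (the gap between the lower credibility bound of
    between-gene tree distances and the upper critical value of the coalescent
    null), a sequential taxon-removal search for the smallest set of putative
    hybrid individuals, species-tree inference by minimizing deep coalescences,
    chronogram scaling, effective-population-size arithmetic from theta and
    mutation rates, and a fully seeded synthetic-scenario generator so the
    whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
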