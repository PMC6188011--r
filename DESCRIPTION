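Package: paleorich
Title: Time-Sliced Lineage Richness from Fossil Ranges and Cladograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating per-interval lineage richness of fossil
    clades while propagating stratigraphic age uncertainty and ghost lineages
    implied by a phylogeny. Provides maximum and minimum lineage-count curves
    on a regular time grid, envelopes over sets of equally parsimonious trees,
    polytomy-resolution enumeration, attachment of taxa not sampled in the
    character matrix, maximum-parsimony scoring and heuristic search for
    morphological matrices with ordered (additive) characters, a birth-death
    fossil-record simulator for validation, and the packaged walrus
    (Odobenidae) chronostratigraphic range and cladogram fixtures the methods
    were developed on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
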