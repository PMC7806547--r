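Package: guildscan
Title: Guild-Based Co-Abundance Analysis of Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-abundant groups (CAGs, "guilds") of amplicon sequence
    variants from microbiome count tables. Implements SparCC basis-correlation
    inference for compositional counts, Ward clustering of the 1 - r SparCC
    distance, recursive PERMANOVA tree-cutting into guilds, and association of
    guild abundances with host phenotypes and short-chain fatty acids.
    Includes rarefaction and prevalence filtering, alpha/beta diversity with
    group-level permutation tests, Cytoscape-compatible network export, and a
    synthetic-data generator with planted guild structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
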