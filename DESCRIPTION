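Package: reefwater
Title: Diversity, Co-Occurrence and Community Assembly Analysis for
    Coral-Habitat Seawater Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible implementation of the statistical inference
    chain used to study bacterial and carbon-fixing bacterial communities
    in coral-habitat seawater: alpha diversity (richness, Chao1, Shannon,
    Gini-Simpson), Bray-Curtis beta diversity with NMDS ordination and
    ANOSIM, Hellinger-transformed redundancy analysis with stepwise
    forward selection, Mantel and partial Mantel tests, Random-Forest
    selection of key taxa, ensemble co-occurrence network inference with
    a compositionality-corrected permutation null, and phylogenetic
    null-model inference of community assembly processes via
    abundance-weighted betaMNTD and betaNTI.  Includes a synthetic
    community generator (Yule phylogenies, Brownian niche traits,
    environmental filtering versus neutral sampling) so the whole
    pipeline can be exercised end to end with known ground truth, plus
    strict readers and writers for OTU tables, Newick trees and sample
    metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
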