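Package: ceq
Title: Entity-Quality Annotation Profiles for Cell Phenotypes and Cell
    Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents cell phenotypes and cell-mechanism changes as
    entity-quality (EQ) annotation profiles over two interlinked
    ontologies: an ontology of cell parts (continuants) and an ontology of
    cell mechanisms (occurrents), each built from is_a and all-some
    has_part relations. Provides polarity-aware annotation propagation
    (positive annotations flow from wholes to necessary parts, 'absent'
    flows contrapositively from parts to wholes), corpus-based information
    content, Resnik-style term and profile similarity with best-match
    averaging and simGIC, ranked similarity search over profile corpora,
    derivation of mechanism-change profiles from pairs of time-stamped
    phenotype profiles by qualitative differential analysis, and
    hierarchical clustering of profiles. Ships deterministic example
    ontologies and profiles for the epithelial/mesenchymal transition
    (MET/EMT) domain, a seeded synthetic corpus generator with planted
    cluster structure, and readers/writers for an OBO 1.4 subset and a
    profile TSV layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
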