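Package: sepminer
Title: Mining and Relational Characterization of Drug Side-Effect Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers side-effect profiles (SEPs) as maximal frequent
    itemsets of semantically coherent side-effect term clusters shared by
    many drugs, and characterizes each profile with two explicit learners:
    a binary-split decision tree over single-table drug descriptors and a
    mode-directed relational rule inducer operating on a drug/target
    knowledge base (targets, protein-protein interactions, GO annotations,
    pathways, domains). Includes hierarchy-based semantic similarity and
    Ward clustering of side-effect terms with automatic cut selection, a
    size-dependent drug-to-cluster association heuristic, stratified
    cross-validation, a report-based checking procedure for predicted
    false positives, and a synthetic relational data generator with
    planted profiles and rules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    foreign,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
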