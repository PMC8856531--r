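Package: mrpsupertree
Title: Matrix Representation with Parsimony Supertrees with Input-Tree
    Curation and Clade Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genus- or species-level supertrees from collections of
    published rooted phylogenies using matrix representation with parsimony
    (MRP).  Provides a curation protocol that reduces pseudoreplication
    among input trees sharing underlying data (50% taxon-overlap rule,
    preference for comprehensive trees, fractional down-weighting of tied
    alternatives, singleton-taxon removal), Baum-Ragan binary coding with
    exact per-character weights and NEXUS export, weighted Fitch parsimony
    scoring with heuristic tree search (random addition sequences and NNI,
    SPR or TBR branch swapping) plus an exhaustive oracle for small
    problems, strict and majority-rule consensus, V and V+ supertree
    support indices with collapsing of unsupported novel clades, nested
    data partitions with placeholder taxa, and a synthetic input-tree
    generator for end-to-end validation against a known model tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    generics,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    igraph,
    yaml,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
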