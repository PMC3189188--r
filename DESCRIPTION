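Package: phyloweave
Title: Simulating Gene-Sharing Highways and Weaving Gene Trees into
    Reticulated Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how horizontal gene transfer distorts
    phylogenomic reconstruction and for building reticulated phylogenetic
    networks on a rooted scaffold tree. Includes a continuous-time Markov
    chain protein sequence simulator under the JTT model with a directed
    highway of ortholog replacement between designated donor and recipient
    lineages; Kimura-corrected protein distances and deterministic
    neighbor-joining; supermatrix concatenation; embedded-quartet
    decomposition of gene trees with plurality supertree assembly (exact
    exhaustive search for small taxon sets and a quartet-joining heuristic);
    a congruence screen that detects highly supported conflicting
    bipartitions among gene trees and classifies them by taxonomic rank;
    and superposition of gene-family trees onto a rooted scaffold to emit
    a network of vertical tree edges plus directed reticulation edges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    optparse,
    phytools,
    withr
Config/testthat/edition: 3
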