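Package: netprio
Title: Betweenness-Based Gene Prioritization in Disease Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Prioritizes genes by comparing their betweenness centrality in a
    disease-specific protein-protein interaction subnetwork (seed genes plus
    first neighbors, pruned of single-degree non-seed nodes, restricted to the
    giant component) against degree-stratified random background networks
    built by resampling seed sets from contiguous degree intervals of the full
    interactome. Per-gene empirical p-values (r+1)/(n+1) are adjusted with the
    Benjamini-Hochberg procedure; cross-network overlap of novel candidates is
    assessed with a hypergeometric test. Includes readers for generic,
    BioGRID-style and HPRD-style edge lists, a synthetic scale-free fixture
    generator with planted low-degree bridge genes, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
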