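Package: mpsampler
Title: Multi-Protein Similarity-Based Sampling of Representative Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects representative genomes from large collections using
    families of homologous single-copy proteins. Sequences are clustered
    within each family (k-mer prefilter, local-alignment verification,
    greedy set cover), genomes are summarised as vectors of cluster labels
    and collapsed into elementary groups of genomes (EGGs), pairwise Dice
    similarities between EGGs are computed blockwise through a sparse
    one-hot encoding, EGGs are agglomerated by complete-linkage clustering
    cut at a minimum similarity threshold, and one representative genome
    per cluster is chosen by a deterministic priority cascade (user score,
    protein-family completeness, centrality, hash-based tie-break).
    Includes an optional pre-connection step that partitions EGGs into
    rough components before similarity computation, taxonomic-diversity
    and phylogenetic-diversity evaluation of the resulting samples, a
    worked-example fixture and a generator of synthetic protein families
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
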