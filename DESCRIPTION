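Package: phagetools
Title: Quantitative Analysis of Broad-Host-Range Phage Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative and ecological analysis of a
    collection of phages and their bacterial hosts. Scores cross-infection
    titer matrices with the Paired Difference Index (PDI) and derives host
    susceptibility classes; builds best-bidirectional-hit (BBH) gene
    families and an adjacency-weighted pangenome graph from annotated
    genomes; classifies genomes into family/genus/species ranks from an
    intergenomic similarity matrix; reconstructs gene gain and loss by
    Dollo parsimony; maps homologous-recombination events onto core-gene
    coordinates and tests the association between core-gene divergence,
    recombination and dN/dS; estimates adsorption rate, latent period and
    burst size from kinetic titer series; and simulates all of these
    inputs with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Biostrings,
    IRanges,
    BiocGenerics,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
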