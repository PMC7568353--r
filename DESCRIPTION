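Package: pangraphr
Title: Reference Pangenome Graphs: rGFA Model, Sequence-to-Graph Mapping and
    Incremental Structural-Variant Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A bidirected sequence-graph data model with the rGFA stable
    coordinate extension, a minimizer-based sequence-to-graph mapper writing
    GAF (anchor chaining with a dynamic range-min-query tree, linear and
    graph chaining), incremental pangenome-graph construction that augments
    a linear reference backbone with structural variants (100 bp - 100 kb)
    discovered from assemblies, bubble (variation) enumeration with allele
    extraction, blacklist-region interval algebra, and a seeded synthetic
    data generator for references, SV-mutated assemblies and long reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    BiocGenerics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
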