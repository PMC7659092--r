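Package: hingo
Title: Hierarchical Gene Ontology Annotation of Circular RNAs from
    Heterogeneous Network Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotates circular RNAs (circRNAs) with Gene Ontology (GO)
    biological-process terms by transfer across a heterogeneous
    circRNA-protein network. The package builds a typed network from
    circRNA co-expression (Pearson correlation), circRNA-protein
    associations and STRING-style protein-protein interactions, learns
    meta-path aware node embeddings with a HIN2Vec-style random-walk and
    negative-sampling model, trains a GO-DAG-consistent hierarchical
    multi-label neural classifier on protein annotations, transfers the
    trained classifier to circRNA nodes, and evaluates predictions with
    the CAFA-style threshold-swept precision/recall/Fmax protocol. A
    planted-partition synthetic world generator produces all inputs with
    known functional structure so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
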