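Package: pathmincut
Title: Multi-Target Drug Candidate Genes via Pathway Min-Cut
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate target genes (CTGs) for multi-target drug
    design by computing exact s-t minimum cuts on directed disease-pathway
    networks augmented with directed protein-protein interaction (PPI)
    edges. Provides readers for KGML (KEGG pathway XML), tabular edge lists
    and GraphML; PPI augmentation with before/after density statistics; an
    Edmonds-Karp max-flow/min-cut core with a brute-force partition oracle;
    per-disease (source, sink) pair enumeration and CTG occurrence-rate
    reports; degree and HITS-hub centrality baselines with a cut-edge-ratio
    disruption metric; and a seeded directed scale-free network simulator
    used for benchmarking and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
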