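Package: modiplex
Title: Multi-Omics Multiplex Network Diffusion and Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers omics-specific gene association networks from multi-omics
    matrices (correlation tests for quantitative layers, Fisher's exact
    co-occurrence tests for binary layers), assembles them with drug-target
    links into a multiplex heterogeneous network, diffuses from every node
    with random walk with restart to obtain a shared gene-drug similarity
    space, and supports spectral embedding, clustering, local
    over-representation analysis, per-layer contribution trace-back and
    silhouette-based functional evaluation. Includes a synthetic multi-omics
    generator with planted gene modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    uwot
Config/testthat/edition: 3
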