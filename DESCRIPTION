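Package: neutrotex
Title: Neutrosophic Multi-Scale Noise-Resistant Texture Descriptors for
    Content-Based Image Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the MsNrRiTxP family of multi-scale, noise-resistant,
    rotation-invariant texture descriptors from grayscale images after
    transforming them into the neutrosophic domain (truth, indeterminacy and
    falsity membership images), and ranks database images against a query
    with the extended Canberra distance. Includes retrieval evaluation
    (average precision and recall at depth, F-score, mean average precision,
    coefficient of variation across noise conditions), a seeded synthetic
    texture generator with an additive white Gaussian noise corruption
    protocol for end-to-end benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
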