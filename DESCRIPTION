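Package: nestedGrassmann
Title: Nested Grassmann Dimensionality Reduction for Subspace and Planar Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Dimensionality reduction for data lying on real or complex
    Grassmann manifolds via nested Grassmann submanifolds: unsupervised and
    supervised fitting of embeddings span(AX + B) between Grassmannians of
    different ambient dimension, the full principal nested Grassmann chain
    down to Gr(1, 2) with its nested Grassmann mean and principal scores,
    and a tangent-PCA (principal geodesic analysis) baseline.  Includes a
    Kendall planar-shape front end mapping landmark configurations to the
    complex projective representation, a seeded synthetic-data generator,
    plain-text dataset input/output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
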