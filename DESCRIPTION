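Package: wfclust
Title: Multi-Scale Weber-Fechner Clustering for Massive Point and
    Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-scale hierarchical clustering driven by the
    Weber-Fechner law: the similarity threshold between successive
    observation scales grows geometrically by a constant just-noticeable
    fraction lambda, and at every scale points whose similarity meets the
    threshold are linked and connected components are reported as
    clusters.  Low-dimensional data are handled by splicing/decomposable
    (SD) grid coding with Chebyshev-adjacent cell linking in linear time;
    high-dimensional data (for example single-cell expression profiles)
    by dimension-marker (DM) binary coding with Jaccard similarity
    retrieved sub-quadratically through MinHash signatures and
    locality-sensitive-hashing banding.  Includes cluster hierarchy
    assembly across scales, purity and F1 validation measures,
    highly-variable-gene and density preprocessing, synthetic benchmark
    generators with planted structure, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
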