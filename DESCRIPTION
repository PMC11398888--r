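Package: fosda
Title: Discriminant Analysis for Functional Data on Random Surface Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of functions on surfaces (FoSs): pairs of a
    closed triangle-mesh geometry and a vertex-valued scalar map, such as
    cortical surfaces coupled with cortical thickness. Each pair is
    represented linearly as an RKHS velocity field deforming a common
    template plus a spatially normalized map, and a penalized
    least-squares functional linear discriminant direction is estimated
    with Laplace-Beltrami differential regularization, discretized by
    linear finite elements and solved as a sparse augmented least-squares
    problem. Includes an approximate functional quadratic discriminant
    extension, model selection by validation AUC, a synthetic-data
    generator with known ground truth, mesh and map I/O, and an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
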