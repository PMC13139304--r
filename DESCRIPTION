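Package: dentopo
Title: Dental Topographic Metrics and Diet Classification from Tooth Crown Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes dental topographic metrics from triangulated lower-molar
    crown surfaces (relief index, Dirichlet normal energy and its convex and
    bandwidth-robust ariaDNE variants, orientation patch count rotated, occlusal
    outline area) together with a 2D trigonid-talonid height index measured on
    the lingual silhouette, and infers diet from them with equal-prior quadratic
    discriminant analysis under leave-one-out and clade-based cross-validation.
    Includes mesh readers and writers (PLY, OBJ, OFF), the standard
    mesh-conditioning chain (cleaning, centring, quadric decimation, HC
    Laplacian smoothing), normality-gated univariate comparison procedures,
    unit-variance PCA, and parametric generators for cusped crown surfaces and
    diet-structured feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    methods,
    stats,
    tools,
    utils,
    Matrix,
    MASS,
    car,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
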