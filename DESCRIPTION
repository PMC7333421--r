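Package: cisrrr
Title: Coordinate-Independent Sparse Reduced-Rank Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Row-sparse, low-rank estimation for multivariate linear
    regression via a group Dantzig-type convex program. The coefficient
    matrix is factored as C = B t(A) with A an orthonormal basis of the
    right singular subspace of the responses, and B is estimated by
    minimising the sum of row 2-norms subject to a bound on the largest
    row-wise l1 correlation between predictors and residuals. Includes
    alternating subspace refinement with SVD- and ridge-based
    initialisation, cross-validated selection of the sparsity parameter
    and the rank, bootstrap stability selection, a simulation engine for
    AR(1)-correlated designs with row-sparse low-rank signal, and a
    downstream genetic-risk-score / two-stage Mendelian-randomization
    pipeline for SNP-metabolomics integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
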