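# Independent oracles kept free of the code paths they check.

# Brute-force Gaussian classifier: per-class multivariate normal density
# evaluated directly (determinant + solve), no discriminant shortcut, no
# Cholesky caching.
bruteForceGaussianPredict <- function(table, features, newdata,
                                      class_col = "diet") {
  X <- as.matrix(table[, features, drop = FALSE])
  y <- as.character(table[[class_col]])
  classes <- sort(unique(y))
  dens <- sapply(classes, function(k) {
    Xi <- X[y == k, , drop = FALSE]
    mu <- colMeans(Xi)
    S <- cov(Xi)
    p <- ncol(Xi)
    apply(as.matrix(newdata[, features, drop = FALSE]), 1, function(x) {
      d <- x - mu
      exp(-0.5 * drop(t(d) %*% solve(S, d))) /
        sqrt((2 * pi)^p * det(S))
    })
  })
  dens <- matrix(dens, ncol = length(classes),
                 dimnames = list(NULL, classes))
  # equal priors cancel; argmax of density with lexicographic tie-break
  classes[apply(dens, 1, which.max)]
}

.checkWindingsExported <- function(mesh) dentopo:::.checkWindings(meshFaces(mesh))
.meshVolumeExported <- function(mesh)
  dentopo:::.meshVolume(meshVertices(mesh), meshFaces(mesh))

# Polygon area by the shoelace formula (outline-area cross-check).
shoelaceArea <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}
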