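# Dirichlet normal energy of the vertex-normal map. Per face, the energy
# density e(p) = tr(G^-1 H) is computed from the first fundamental form G of
# the embedding and the corresponding form H of the angle-weighted
# vertex-normal field; DNE = sum over included faces of e(p) * a(p). The
# quantity is scale-free: e scales as 1/s^2 under uniform scaling by s while
# the area weight scales as s^2.

#' Dirichlet normal energy
#'
#' @param mesh a [ToothMesh-class] with consistent face windings.
#' @param boundary_exclude logical; exclude faces with an edge on an open
#'   boundary (default `TRUE`, the convention for cropped crowns).
#' @param outlier_fraction proportion of included faces with the highest
#'   energy x area to exclude (default 0.001, i.e. the top 0.1 percent).
#' @param variant `"total"` (default) or `"convex"`; the convex variant sums
#'   only over faces whose discrete mean curvature indicates outward-facing
#'   (convex) curvature, i.e. the cutting surfaces.
#' @return list with elements `dne` (the scalar energy) and `field`, a
#'   per-face data frame (`energy`, `area`, `excluded`, `convex`).
#' @examples
#' # a flat patch has zero energy
#' m <- toothMesh(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)),
#'                rbind(c(1,2,3), c(1,3,4)))
#' computeDNE(m)$dne
#' @export
computeDNE <- function(mesh, boundary_exclude = TRUE, outlier_fraction = 0.001,
                       variant = c("total", "convex")) {
  variant <- match.arg(variant)
  validObject(mesh)
  if (!.checkWindings(mesh@faces))
    stop("orientation error: mesh has inconsistent face windings")
  v <- mesh@vertices
  f <- mesh@faces
  vn <- .vertexNormals(v, f)
  p1 <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - p1
  w <- v[f[, 3], , drop = FALSE] - p1
  n1 <- vn[f[, 1], , drop = FALSE]
  nu <- vn[f[, 2], , drop = FALSE] - n1
  nw <- vn[f[, 3], , drop = FALSE] - n1
  guu <- rowSums(u * u); guv <- rowSums(u * w); gvv <- rowSums(w * w)
  huu <- rowSums(nu * nu); huv <- rowSums(nu * nw); hvv <- rowSums(nw * nw)
  det <- guu * gvv - guv^2
  e <- (gvv * huu - 2 * guv * huv + guu * hvv) / det
  e[!is.finite(e) | det <= .Machine$double.eps * (guu + gvv)^2] <- 0
  a <- .faceAreas(v, f)

  # discrete mean-curvature sign: normals diverging along outward
  # displacement => convex. Ties (|kappa| < 1e-12) count as convex.
  kap <- rowSums((vn[f[, 2], ] - vn[f[, 1], ]) * u) +
         rowSums((vn[f[, 3], ] - vn[f[, 2], ]) * (v[f[, 3], ] - v[f[, 2], ])) +
         rowSums((vn[f[, 1], ] - vn[f[, 3], ]) * (v[f[, 1], ] - v[f[, 3], ]))
  convex <- kap > -1e-12

  excluded <- rep(FALSE, nrow(f))
  if (boundary_exclude) {
    bf <- .boundaryFaces(f)
    excluded[bf] <- TRUE
  }
  if (outlier_fraction > 0) {
    contrib <- e * a
    contrib[excluded] <- -Inf
    nOut <- ceiling(outlier_fraction * sum(!excluded))
    if (nOut > 0) {
      ord <- order(contrib, decreasing = TRUE)
      excluded[ord[seq_len(nOut)]] <- TRUE
    }
  }
  include <- !excluded
  if (variant == "convex") include <- include & convex
  dne <- sum(e[include] * a[include])
  list(dne = dne,
       field = data.frame(energy = e, area = a, excluded = excluded,
                          convex = convex))
}

#' Bandwidth-robust curvature energy (ariaDNE) and its coefficient of
#' variation
#'
#' The mesh is rescaled to unit total surface area, making the Gaussian
#' bandwidth `epsilon` a fraction of the square root of the crown's area.
#' For each vertex a weighted least-squares quadric is fitted over all
#' vertices within the kernel support (weights `exp(-d^2 / epsilon^2)`), and
#' the per-vertex energy density is the sum of squared principal curvatures
#' of the fitted quadric. The scalar energy is the barycentric-area-weighted
#' sum of the densities, and the CV is the area-weighted standard deviation
#' of the densities divided by their area-weighted mean.
#'
#' @param mesh a [ToothMesh-class].
#' @param epsilon Gaussian bandwidth as a fraction of sqrt(total surface
#'   area); default 0.08 (near the upper end of the recommended 0.04-0.1
#'   range, so larger structures dominate). Values outside the recommended
#'   range are computed with a warning.
#' @return list with elements `ariaDNE`, `ariaDNE_CV` and `field` (per-vertex
#'   data frame: `energy`, `area`, `n_neighbours`).
#' @export
computeAriaDNE <- function(mesh, epsilon = 0.08) {
  validObject(mesh)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon > 0)
  if (epsilon < 0.04 || epsilon > 0.1)
    warning(sprintf("epsilon = %g is outside the recommended range [0.04, 0.1]",
                    epsilon))
  v <- mesh@vertices
  f <- mesh@faces
  A <- sum(.faceAreas(v, f))
  if (A <= 0) stop("degenerate input: zero surface area")
  v <- v / sqrt(A)   # unit total surface area
  vn <- .vertexNormals(v, f)
  res <- .cpp_ariadne_energy(v, f - 1L, vn, epsilon)
  e <- res$energy
  a <- res$vertex_area
  if (anyNA(e)) {
    bad <- which(is.na(e))[1]
    if (res$n_neighbours[bad] < 6)
      stop(sprintf(paste0("bandwidth error: vertex %d has only %d neighbours ",
                          "within the kernel support (need >= 6); epsilon = %g ",
                          "is too small for this mesh"),
                   bad, res$n_neighbours[bad], epsilon))
    stop(sprintf("curvature fit failed at vertex %d", bad))
  }
  total <- sum(e * a)
  wm <- total / sum(a)
  if (wm <= .Machine$double.eps) {
    warning("near-zero curvature field; ariaDNE CV reported as 0")
    cv <- 0
  } else {
    wsd <- sqrt(sum(a * (e - wm)^2) / sum(a))
    cv <- wsd / wm
  }
  list(ariaDNE = total, ariaDNE_CV = cv,
       field = data.frame(energy = e, area = a,
                          n_neighbours = res$n_neighbours))
}
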