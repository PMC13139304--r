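# Low-level triangle-mesh geometry shared across modules.

.faceCross <- function(v, f) {
  p1 <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - p1
  w <- v[f[, 3], , drop = FALSE] - p1
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

.faceAreas <- function(v, f) {
  if (nrow(f) == 0) return(numeric(0))
  cr <- .faceCross(v, f)
  0.5 * sqrt(rowSums(cr^2))
}

.faceNormals <- function(v, f, unit = TRUE) {
  cr <- .faceCross(v, f)
  if (!unit) return(cr)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

# Angle-weighted vertex normals: each incident face contributes its unit
# normal weighted by the corner angle at the vertex.
.vertexNormals <- function(v, f) {
  fn <- .faceNormals(v, f)
  n <- matrix(0, nrow(v), 3)
  ang <- matrix(0, nrow(f), 3)
  for (c1 in 1:3) {
    c2 <- c1 %% 3 + 1
    c3 <- (c1 + 1) %% 3 + 1
    e1 <- v[f[, c2], , drop = FALSE] - v[f[, c1], , drop = FALSE]
    e2 <- v[f[, c3], , drop = FALSE] - v[f[, c1], , drop = FALSE]
    l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
    cosv <- rowSums(e1 * e2) / pmax(l1 * l2, .Machine$double.xmin)
    ang[, c1] <- acos(pmin(1, pmax(-1, cosv)))
  }
  for (c1 in 1:3) {
    w <- ang[, c1] * fn
    for (d in 1:3) {
      acc <- rowsum(w[, d], f[, c1])
      n[as.integer(rownames(acc)), d] <- n[as.integer(rownames(acc)), d] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# Directed edge table (3m x 2) in face winding order.
.directedEdges <- function(f) {
  rbind(f[, c(1, 2), drop = FALSE],
        f[, c(2, 3), drop = FALSE],
        f[, c(3, 1), drop = FALSE])
}

.edgeKeys <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
}

# Faces with at least one edge on an open boundary (undirected edge used once).
.boundaryFaces <- function(f) {
  e <- .directedEdges(f)
  key <- .edgeKeys(e)
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  fid <- rep(seq_len(nrow(f)), 3)
  unique(fid[key %in% bkey])
}

# Vertex-connected components; returns per-face component id.
.faceComponents <- function(v, f) {
  parent <- seq_len(nrow(v))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(f))) {
    a <- find(f[r, 1]); b <- find(f[r, 2]); c <- find(f[r, 3])
    parent[b] <- a; parent[find(c)] <- find(a)
  }
  roots <- vapply(f[, 1], find, integer(1))
  match(roots, unique(roots))
}

# Winding consistency: within each component no undirected edge may be
# traversed twice in the same direction (that would mean two adjacent faces
# with opposite outward sides, or a duplicated face).
.checkWindings <- function(f) {
  if (nrow(f) == 0) return(TRUE)
  e <- .directedEdges(f)
  dkey <- paste(e[, 1], e[, 2], sep = "_")
  !anyDuplicated(dkey)
}

#' Validate a tooth mesh
#'
#' Runs the full mesh validity check: structural validity (in-range, distinct,
#' non-degenerate faces; enforced by the class) plus winding consistency
#' within each connected component.
#'
#' @param mesh a [ToothMesh-class].
#' @param windings logical; also require consistent face windings.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validateMesh <- function(mesh, windings = TRUE) {
  validObject(mesh)
  if (windings && !.checkWindings(mesh@faces))
    stop("mesh has inconsistent face windings (or duplicate faces) within a component")
  invisible(TRUE)
}

#' Heuristically orient a crown mesh occlusally
#'
#' Aligns the axis of minimal projected extent (smallest principal axis of the
#' vertex scatter) with +z, so that the chewing surface faces up, and flips z
#' so that the vertex-mass skew points upwards. This is a heuristic stand-in
#' for manual orientation and should be checked visually for real specimens;
#' the mesial (+x) direction is not resolved and may need a manual flip.
#'
#' @param mesh a [ToothMesh-class].
#' @return The rotated mesh with `isOriented(mesh)` set to `TRUE`.
#' @export
orientOcclusally <- function(mesh) {
  v <- mesh@vertices
  ev <- eigen(stats::cov(v), symmetric = TRUE)
  R <- ev$vectors[, c(1, 2, 3)]  # columns: decreasing variance; last -> z
  if (det(R) < 0) R[, 3] <- -R[, 3]
  v2 <- v %*% R
  # put the long tail of the height distribution (cusps) on the +z side
  z <- v2[, 3] - mean(v2[, 3])
  if (sum(z^3) < 0) v2[, c(2, 3)] <- -v2[, c(2, 3)]
  toothMesh(v2, mesh@faces, oriented = TRUE)
}

# Uniform scale + rigid transform helpers used in tests and invariance checks.

#' Affine helpers for meshes
#'
#' `scaleMesh` applies a uniform scale factor; `rotateMeshZ` rotates about the
#' +z axis by an angle in degrees; `translateMesh` adds an offset.
#'
#' @param mesh a [ToothMesh-class].
#' @param s scale factor.
#' @param degrees rotation angle about +z.
#' @param offset numeric length-3 translation.
#' @return The transformed mesh (orientation flag preserved).
#' @export
scaleMesh <- function(mesh, s) {
  stopifnot(is.numeric(s), length(s) == 1, s > 0)
  toothMesh(mesh@vertices * s, mesh@faces, oriented = mesh@oriented)
}

#' @rdname scaleMesh
#' @export
rotateMeshZ <- function(mesh, degrees) {
  th <- degrees * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  toothMesh(mesh@vertices %*% t(R), mesh@faces, oriented = mesh@oriented)
}

#' @rdname scaleMesh
#' @export
translateMesh <- function(mesh, offset) {
  stopifnot(length(offset) == 3)
  toothMesh(sweep(mesh@vertices, 2, offset, "+"), mesh@faces,
            oriented = mesh@oriented)
}

# Enclosed volume of a closed mesh (divergence theorem; signed).
.meshVolume <- function(v, f) {
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p3[, 2] * p2[, 3]) -
      p2[, 1] * (p1[, 2] * p3[, 3] - p3[, 2] * p1[, 3]) +
      p3[, 1] * (p1[, 2] * p2[, 3] - p2[, 2] * p1[, 3])) / 6
}
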