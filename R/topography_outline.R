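# Occlusal outline area via 2D alpha shapes built on a Delaunay alpha
# complex. In "auto" mode the bandwidth sweep follows a fixed rule: 64
# log-spaced alpha values between 0.01x and 10x the median projected edge
# length; the smallest alpha whose complex is a single simple polygon without
# holes that carries every projected vertex wins; the convex hull is the
# declared (and logged) fallback when no alpha qualifies.

.triCircumradius <- function(p, tri) {
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  c <- p[tri[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c)^2))
  lb <- sqrt(rowSums((a - c)^2))
  lc <- sqrt(rowSums((a - b)^2))
  ar <- abs((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
            (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
  r <- la * lb * lc / (4 * ar)
  r[ar <= 0] <- Inf
  r
}

.triAreas2d <- function(p, tri) {
  a <- p[tri[, 1], , drop = FALSE]
  b <- p[tri[, 2], , drop = FALSE]
  c <- p[tri[, 3], , drop = FALSE]
  abs((b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
      (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])) / 2
}

# Qualification test for an alpha complex: connected, no holes (Euler), the
# boundary is a simple cycle, and every input point is carried.
.alphaComplexOk <- function(tri, keep, npts) {
  if (!any(keep)) return(FALSE)
  kt <- tri[keep, , drop = FALSE]
  if (length(setdiff(seq_len(npts), unique(as.vector(kt)))) > 0) return(FALSE)
  # single edge-connected component of triangles
  e <- rbind(kt[, 1:2], kt[, 2:3], kt[, c(3, 1)])
  key <- .edgeKeys(e)
  fid <- rep(seq_len(nrow(kt)), 3)
  tb <- split(fid, key)
  parent <- seq_len(nrow(kt))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (g in tb) if (length(g) >= 2)
    for (k in 2:length(g)) { a <- find(g[1]); b <- find(g[k]); parent[b] <- a }
  if (length(unique(vapply(seq_len(nrow(kt)), find, integer(1)))) != 1) return(FALSE)
  # Euler characteristic of a triangulated disc: V - E + T = 1 (no holes)
  nV <- length(unique(as.vector(kt)))
  nE <- length(tb)
  nT <- nrow(kt)
  if (nV - nE + nT != 1L) return(FALSE)
  # boundary must be a simple cycle: every boundary vertex on exactly 2 bnd edges
  bnd <- names(tb)[lengths(tb) == 1L]
  bv <- unlist(strsplit(bnd, "_"))
  if (any(table(bv) != 2L)) return(FALSE)
  TRUE
}

# Ordered boundary cycle (vertex indices into p) of a kept triangle set.
.alphaBoundary <- function(tri, keep) {
  kt <- tri[keep, , drop = FALSE]
  e <- rbind(kt[, 1:2], kt[, 2:3], kt[, c(3, 1)])
  key <- .edgeKeys(e)
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  be <- do.call(rbind, strsplit(bkey, "_"))
  be <- matrix(as.integer(be), ncol = 2)
  nb <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  start <- min(be)
  cyc <- integer(nrow(be))
  cyc[1] <- start
  prev <- -1L
  cur <- start
  for (i in 2:length(cyc)) {
    nxt <- setdiff(nb[[as.character(cur)]], prev)[1]
    cyc[i] <- nxt
    prev <- cur
    cur <- nxt
  }
  cyc
}

# Shared alpha-shape machinery on 2D points. Returns area, the kept triangle
# set, boundary cycle and the alpha used (NA for a convex-hull fallback).
.alphaShape <- function(p, alpha = "auto", medianEdge = NULL) {
  p <- p[!duplicated(round(p, 12)), , drop = FALSE]
  n <- nrow(p)
  if (n < 3) stop("degenerate projection: fewer than 3 distinct points")
  rng <- apply(p, 2, function(col) diff(range(col)))
  far <- which.max((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
  crossMax <- max(abs((p[far, 1] - p[1, 1]) * (p[, 2] - p[1, 2]) -
                      (p[far, 2] - p[1, 2]) * (p[, 1] - p[1, 1])))
  if (max(rng) == 0 || crossMax < 1e-12 * max(rng)^2)
    stop("degenerate projection: points are collinear")
  tri <- .cpp_delaunay(p) + 1L
  if (nrow(tri) == 0) stop("degenerate projection: triangulation is empty")
  r <- .triCircumradius(p, tri)
  areas <- .triAreas2d(p, tri)
  hullFallback <- function() {
    h <- grDevices::chull(p)
    hp <- p[h, , drop = FALSE]
    a <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                 hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
    message("alpha sweep found no qualifying alpha; falling back to the convex hull")
    list(area = a, points = p, keep = r <= Inf, tri = tri,
         boundary = h, alpha = NA_real_)
  }
  if (identical(alpha, "auto")) {
    if (is.null(medianEdge)) {
      ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
      medianEdge <- stats::median(sqrt(rowSums((p[ed[, 1], ] - p[ed[, 2], ])^2)))
    }
    grid <- exp(seq(log(0.01 * medianEdge), log(10 * medianEdge), length.out = 64))
    for (a in grid) {
      keep <- r <= a
      if (.alphaComplexOk(tri, keep, n)) {
        return(list(area = sum(areas[keep]), points = p, keep = keep, tri = tri,
                    boundary = .alphaBoundary(tri, keep), alpha = a))
      }
    }
    hullFallback()
  } else {
    stopifnot(is.numeric(alpha), alpha > 0)
    keep <- r <= alpha
    if (!.alphaComplexOk(tri, keep, n)) return(hullFallback())
    list(area = sum(areas[keep]), points = p, keep = keep, tri = tri,
         boundary = .alphaBoundary(tri, keep), alpha = alpha)
  }
}

#' 2D occlusal outline area
#'
#' Projects the mesh vertices onto the occlusal plane (z = 0) and returns the
#' area of their alpha-shape polygon. With `alpha = "auto"` the smallest
#' alpha on a 64-point log grid (0.01x to 10x the median projected edge
#' length) whose complex is a single simple hole-free polygon enclosing all
#' projected vertices is used; if none qualifies the convex hull is used and
#' a message is emitted.
#'
#' @param mesh an occlusally oriented [ToothMesh-class].
#' @param alpha `"auto"` (default) or a positive numeric alpha radius.
#' @return outline area (squared length units).
#' @export
outlineArea <- function(mesh, alpha = "auto") {
  validObject(mesh)
  p <- mesh@vertices[, c(1, 2), drop = FALSE]
  ed <- .directedEdges(mesh@faces)
  medianEdge <- stats::median(sqrt(rowSums(
    (mesh@vertices[ed[, 1], 1:2] - mesh@vertices[ed[, 2], 1:2])^2)))
  if (medianEdge == 0) medianEdge <- NULL
  .alphaShape(p, alpha = alpha, medianEdge = medianEdge)$area
}

#' Relief index
#'
#' RFI = ln( sqrt(3D crown surface area) / sqrt(2D occlusal outline area) ).
#' Zero for a flat patch, ln(sqrt(2)) for a hemisphere, and invariant to
#' uniform scaling.
#'
#' @inheritParams outlineArea
#' @return RFI (dimensionless).
#' @export
computeRFI <- function(mesh, alpha = "auto") {
  a3 <- surfaceArea(mesh)
  a2 <- outlineArea(mesh, alpha = alpha)
  if (a2 <= 0) stop("degenerate outline: zero outline area")
  log(sqrt(a3) / sqrt(a2))
}
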