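# Mesh-conditioning chain: clean + centre, decimate to a fixed triangle
# budget, HC Laplacian smoothing. Every operation emits a PreprocessReport so
# a run leaves an audit trail of what was removed or changed.

.preprocessReport <- function(faces_before, faces_after, components_removed = 0L,
                              duplicates_removed = 0L, was_downsampled = FALSE,
                              smoothing_passes = 0L) {
  structure(list(faces_before = faces_before, faces_after = faces_after,
                 components_removed = components_removed,
                 duplicates_removed = duplicates_removed,
                 was_downsampled = was_downsampled,
                 smoothing_passes = smoothing_passes),
            class = "PreprocessReport")
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat(sprintf(paste0("PreprocessReport: %d -> %d faces",
                     " (duplicates removed: %d, components removed: %d,",
                     " downsampled: %s, smoothing passes: %d)\n"),
              x$faces_before, x$faces_after, x$duplicates_removed,
              x$components_removed, x$was_downsampled, x$smoothing_passes))
  invisible(x)
}

#' Remove duplicate faces and isolated pieces, centre the mesh
#'
#' Duplicate faces (same vertex triple in any order) are dropped, only the
#' largest connected component by face count is retained, unreferenced
#' vertices are pruned, and the vertex centroid is translated to the origin.
#'
#' @param mesh a [ToothMesh-class].
#' @return list with elements `mesh` (cleaned [ToothMesh-class]) and `report`
#'   (a `PreprocessReport`).
#' @export
cleanAndCenter <- function(mesh) {
  validObject(mesh)
  f <- mesh@faces
  v <- mesh@vertices
  nf0 <- nrow(f)
  if (nf0 == 0) stop("degenerate input: mesh has no faces")
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  dup <- duplicated(key)
  f <- f[!dup, , drop = FALSE]
  ndup <- sum(dup)

  comp <- .faceComponents(v, f)
  ncomp <- max(comp)
  removed <- 0L
  if (ncomp > 1) {
    sizes <- tabulate(comp)
    keep <- which.max(sizes)
    f <- f[comp == keep, , drop = FALSE]
    removed <- ncomp - 1L
  }
  if (nrow(f) == 0) stop("degenerate input: mesh empty after cleaning")

  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap[f], ncol = 3)
  v <- sweep(v, 2, colMeans(v), "-")

  out <- toothMesh(v, f, oriented = mesh@oriented)
  list(mesh = out,
       report = .preprocessReport(nf0, nrow(f), components_removed = removed,
                                  duplicates_removed = ndup))
}

#' Downsample a mesh to a fixed triangle budget
#'
#' Quadric edge-collapse decimation to `target_faces` (within two faces).
#' Inputs already at or below the budget are returned unchanged with a
#' warning, mirroring the handling of low-resolution specimens that cannot be
#' downsampled.
#'
#' @param mesh a [ToothMesh-class].
#' @param target_faces target triangle count (default 10000).
#' @return list with elements `mesh` and `report`.
#' @export
simplifyMesh <- function(mesh, target_faces = 10000) {
  validObject(mesh)
  if (!is.numeric(target_faces) || target_faces < 4)
    stop("target_faces must be at least 4")
  target_faces <- as.integer(target_faces)
  nf0 <- nFaces(mesh)
  if (nf0 <= target_faces) {
    warning(sprintf("mesh has %d faces (<= target %d); returned unchanged",
                    nf0, target_faces))
    return(list(mesh = mesh,
                report = .preprocessReport(nf0, nf0, was_downsampled = FALSE)))
  }
  res <- .cpp_qem_decimate(mesh@vertices, mesh@faces - 1L, target_faces)
  out <- toothMesh(res$vertices, res$faces + 1L, oriented = mesh@oriented)
  list(mesh = out,
       report = .preprocessReport(nf0, nFaces(out), was_downsampled = TRUE))
}

#' HC Laplacian smoothing
#'
#' Each pass performs uniform-weight Laplacian averaging followed by the HC
#' back-projection correction of Vollmer, Mencl and Mueller: the mean of the
#' neighbour displacement vectors is subtracted back (correction factors
#' alpha = 0, beta = 0.5), which suppresses the volume shrinkage of plain
#' Laplacian smoothing. Topology is unchanged; flat regions are fixed points.
#'
#' Open-boundary vertices (the cervical margin of a cropped crown) are
#' anchored by default so the crown rim does not creep inwards.
#'
#' @param mesh a [ToothMesh-class].
#' @param passes number of smoothing passes (>= 0; 0 returns the input).
#' @param alpha,beta HC correction factors.
#' @param fix_boundary logical; keep open-boundary vertices fixed (default
#'   `TRUE`).
#' @return The smoothed [ToothMesh-class].
#' @export
smoothHCL <- function(mesh, passes = 1, alpha = 0, beta = 0.5,
                      fix_boundary = TRUE) {
  validObject(mesh)
  stopifnot(passes >= 0)
  if (passes == 0) return(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  e <- .directedEdges(f)
  und <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  n <- nrow(v)
  A <- Matrix::sparseMatrix(i = c(und[, 1], und[, 2]),
                            j = c(und[, 2], und[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  bmask <- logical(n)
  if (fix_boundary) {
    key <- .edgeKeys(e)
    cnt <- table(key)
    bkey <- names(cnt)[cnt == 1L]
    bv <- as.integer(unlist(strsplit(bkey, "_")))
    bmask[bv] <- TRUE
  }
  o <- v  # original positions (alpha-weighted anchor)
  q <- v
  for (it in seq_len(passes)) {
    p <- as.matrix(A %*% q) / deg                 # uniform Laplacian average
    p[bmask, ] <- q[bmask, , drop = FALSE]        # anchor the open boundary
    b <- p - (alpha * o + (1 - alpha) * q)        # displacement field
    p <- p - (beta * b + (1 - beta) * as.matrix(A %*% b) / deg)
    p[bmask, ] <- q[bmask, , drop = FALSE]
    q <- p
  }
  toothMesh(q, f, oriented = mesh@oriented)
}
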