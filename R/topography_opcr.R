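# Orientation patch count rotated. Faces are binned by the azimuth of their
# outward normal into eight 45-degree sectors; edge-connected runs of
# same-sector faces with at least `min_patch_faces` members count as patches;
# the count is averaged over eight rotations of the binning frame in
# 5.625-degree steps (8 rotations x 5.625 degrees = one sector width).

#' Orientation patch count rotated (OPCR)
#'
#' @param mesh an occlusally oriented [ToothMesh-class].
#' @param n_bins number of azimuth sectors (default 8).
#' @param n_rotations number of rotation offsets averaged (default 8).
#' @param rotation_step rotation step in degrees (default 5.625; the scheme
#'   requires `n_rotations * rotation_step` to equal one sector width).
#' @param min_patch_faces minimum faces for a patch to count (default 3).
#' @param flatness_tolerance faces whose unit normal has a horizontal
#'   component below this are treated as flat and excluded (default 1e-4).
#' @return OPCR (mean patch count across rotations; possibly fractional).
#'   The per-rotation counts are attached as attribute `"per_rotation"`.
#' @export
computeOPCR <- function(mesh, n_bins = 8, n_rotations = 8,
                        rotation_step = 5.625, min_patch_faces = 3,
                        flatness_tolerance = 1e-4) {
  validObject(mesh)
  binWidth <- 360 / n_bins
  if (abs(n_rotations * rotation_step - binWidth) > 1e-9)
    warning("n_rotations * rotation_step does not equal one sector width")
  fn <- .faceNormals(mesh@vertices, mesh@faces)
  horiz <- sqrt(fn[, 1]^2 + fn[, 2]^2)
  ok <- horiz >= flatness_tolerance
  az <- (atan2(fn[, 2], fn[, 1]) * 180 / pi) %% 360

  # face adjacency (shared undirected edge)
  f <- mesh@faces
  e <- .directedEdges(f)
  key <- .edgeKeys(e)
  fid <- rep(seq_len(nrow(f)), 3)
  ord <- order(key)
  keyS <- key[ord]; fidS <- fid[ord]
  same <- which(keyS[-length(keyS)] == keyS[-1])
  adj <- cbind(fidS[same], fidS[same + 1])

  counts <- numeric(n_rotations)
  for (r in seq_len(n_rotations)) {
    azr <- (az + (r - 1) * rotation_step) %% 360
    bin <- floor(azr / binWidth)
    bin[!ok] <- NA
    use <- !is.na(bin[adj[, 1]]) & !is.na(bin[adj[, 2]]) &
           bin[adj[, 1]] == bin[adj[, 2]]
    pairs <- adj[use, , drop = FALSE]
    parent <- seq_len(nrow(f))
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
    inc <- which(ok)
    roots <- vapply(inc, find, integer(1))
    sizes <- table(roots)
    counts[r] <- sum(sizes >= min_patch_faces)
  }
  structure(mean(counts), per_rotation = counts)
}
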