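# Lingual-view silhouette and the trigonid-talonid height index. The lingual
# view of an occlusally oriented crown is the projection onto the x-z plane
# (x mesiodistal with +x mesial, z occlusal height), seen from -y. A straight
# baseline joins the mesial and distal cervical endpoints; region heights are
# measured perpendicular to the infinite baseline line, and the maximum molar
# length parallel to it.

#' Lingual-view silhouette of a crown
#'
#' Projects the mesh onto the x-z plane and extracts the boundary polygon
#' (via the auto-alpha shape of the projected vertices), the cervical
#' baseline and the region heights. Baseline endpoints, when supplied, are
#' used verbatim after projection; otherwise they are auto-detected as the
#' lowest-z projected points within the mesial-most and distal-most 15
#' percent of the x extent (ties broken deterministically towards the lower
#' x, with a warning when two candidates are within tolerance).
#'
#' @param mesh an occlusally oriented [ToothMesh-class].
#' @param baseline_points optional 2 x 3 matrix (rows: mesial then distal 3D
#'   points) fixing the cervical endpoints.
#' @param split_fraction position of the trigonid/talonid division along the
#'   baseline, as a fraction of the maximal length measured from the distal
#'   endpoint (default 0.5). The trigonid is the mesial side.
#' @param detection_window fraction of the x extent scanned at each end for
#'   the cervical endpoints (default 0.15).
#' @return A [Silhouette2D-class].
#' @export
lingualSilhouette <- function(mesh, baseline_points = NULL,
                              split_fraction = 0.5, detection_window = 0.15) {
  validObject(mesh)
  if (nFaces(mesh) == 0) stop("empty mesh")
  stopifnot(split_fraction > 0, split_fraction < 1)
  p <- mesh@vertices[, c(1, 3), drop = FALSE]   # (x, z)
  colnames(p) <- c("x", "z")
  shp <- .alphaShape(p)
  outline <- shp$points[shp$boundary, , drop = FALSE]

  if (!is.null(baseline_points)) {
    bp <- as.matrix(baseline_points)
    if (!all(dim(bp) == c(2, 3)))
      stop("baseline_points must be a 2 x 3 matrix of 3D points")
    baseline <- bp[, c(1, 3), drop = FALSE]
  } else {
    xr <- range(p[, 1])
    wind <- detection_window * diff(xr)
    pickLowest <- function(sel) {
      cand <- p[sel, , drop = FALSE]
      zmin <- min(cand[, 2])
      tolz <- 1e-6 * max(diff(range(p[, 2])), .Machine$double.eps)
      low <- cand[cand[, 2] <= zmin + tolz, , drop = FALSE]
      if (nrow(low) > 1 && diff(range(low[, 1])) > tolz)
        warning("ambiguous cervical endpoint; using the lowest-x candidate")
      low[which.min(low[, 1]), ]
    }
    mesial <- pickLowest(p[, 1] >= xr[2] - wind)   # +x = mesial
    distal <- pickLowest(p[, 1] <= xr[1] + wind)
    baseline <- rbind(mesial, distal)
  }
  rownames(baseline) <- c("mesial", "distal")

  h <- .silhouetteHeights(p, baseline, split_fraction)
  new("Silhouette2D", points = p, outline = outline, baseline = baseline,
      splitFraction = split_fraction, hTri = h$hTri, hTal = h$hTal,
      lMax = h$lMax)
}

# Region heights and maximal length relative to a baseline. Positions along
# the baseline are measured from the distal endpoint towards the mesial one;
# heights are signed perpendicular distances with the occlusal side positive.
.silhouetteHeights <- function(p, baseline, split_fraction) {
  dirv <- baseline[1, ] - baseline[2, ]          # distal -> mesial
  len <- sqrt(sum(dirv^2))
  if (len == 0) stop("degenerate baseline: endpoints coincide")
  dirv <- dirv / len
  nrmv <- c(-dirv[2], dirv[1])
  if (nrmv[2] < 0) nrmv <- -nrmv                  # occlusal side positive
  rel <- sweep(p, 2, baseline[2, ], "-")
  tpos <- rel %*% dirv
  height <- rel %*% nrmv
  lMax <- diff(range(tpos))
  if (lMax <= 0) stop("degenerate silhouette: zero length along baseline")
  tau <- (tpos - min(tpos)) / lMax
  triSel <- tau >= split_fraction                 # mesial side
  talSel <- tau <= split_fraction
  if (!any(triSel) || !any(talSel))
    stop("split error: trigonid or talonid region contains no outline points")
  list(hTri = max(0, max(height[triSel])), hTal = max(0, max(height[talSel])),
       lMax = lMax)
}

#' Trigonid-talonid height index
#'
#' TriTaHI = (max trigonid height - max talonid height) / max molar length,
#' with heights measured perpendicular to the cervical baseline and length
#' parallel to it. Positive values indicate a trigonid taller than the
#' talonid; negative values a taller talonid. The index is invariant to
#' uniform scaling, translation and in-plane rotation, and is exactly
#' negated under mesiodistal mirroring.
#'
#' @param sil a [Silhouette2D-class] from [lingualSilhouette()].
#' @param split_fraction optional override of the silhouette's
#'   trigonid/talonid division.
#' @return TriTaHI (dimensionless, in (-1, 1)).
#' @export
computeTriTaHI <- function(sil, split_fraction = NULL) {
  stopifnot(is(sil, "Silhouette2D"))
  if (is.null(split_fraction)) {
    h <- list(hTri = sil@hTri, hTal = sil@hTal, lMax = sil@lMax)
  } else {
    stopifnot(split_fraction > 0, split_fraction < 1)
    h <- .silhouetteHeights(sil@points, sil@baseline, split_fraction)
  }
  (h$hTri - h$hTal) / h$lMax
}
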