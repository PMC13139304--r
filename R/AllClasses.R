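#' Triangulated tooth-crown surface
#'
#' An oriented triangle mesh holding a single lower-molar crown. Vertices are
#' 3D points in consistent (typically mm) units; faces are 1-based triples of
#' vertex indices. When the mesh is occlusally oriented, +z points to the
#' crown apex, +x mesially and +y buccally, so the lingual view is the
#' projection onto the x-z plane seen from -y.
#'
#' Structural validity (checked on construction) requires every face to
#' reference three distinct, in-range vertices and to have non-zero area.
#' Winding consistency within connected components is checked by
#' [validateMesh()], which is applied at read time; it is not part of the
#' structural validity so that cleaning operations can accept meshes with
#' duplicate faces.
#'
#' @slot vertices numeric matrix (n x 3) of vertex coordinates.
#' @slot faces integer matrix (m x 3) of 1-based vertex indices.
#' @slot oriented logical; `TRUE` if the mesh is known to be occlusally
#'   oriented.
#'
#' @seealso [toothMesh()], [readMesh()], [validateMesh()]
#' @export
setClass("ToothMesh",
  representation(vertices = "matrix", faces = "matrix", oriented = "logical"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            oriented = FALSE))

setValidity("ToothMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msgs <- character(0)
  if (ncol(v) != 3) msgs <- c(msgs, "vertices must be an n x 3 matrix")
  if (ncol(f) != 3) msgs <- c(msgs, "faces must be an m x 3 matrix")
  if (!is.numeric(v)) msgs <- c(msgs, "vertices must be numeric")
  if (length(msgs)) return(msgs)
  if (nrow(f) > 0) {
    fm <- matrix(as.integer(f), nrow(f), 3)
    if (anyNA(fm)) msgs <- c(msgs, "faces contain missing indices")
    else {
      bad <- which(fm < 1L | fm > nrow(v), arr.ind = TRUE)
      if (nrow(bad) > 0)
        msgs <- c(msgs, sprintf("face %d references out-of-range vertex index %d",
                                bad[1, 1], fm[bad[1, 1], bad[1, 2]]))
      dup <- which(fm[, 1] == fm[, 2] | fm[, 1] == fm[, 3] | fm[, 2] == fm[, 3])
      if (length(dup))
        msgs <- c(msgs, sprintf("face %d references a repeated vertex index", dup[1]))
      if (!length(msgs)) {
        a <- .faceAreas(v, fm)
        z <- which(a <= 0 | !is.finite(a))
        if (length(z)) msgs <- c(msgs, sprintf("face %d is degenerate (zero area)", z[1]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ToothMesh
#'
#' @param vertices numeric n x 3 matrix of coordinates.
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param oriented logical; is the mesh occlusally oriented?
#' @return A validated [ToothMesh-class] object.
#' @examples
#' m <- toothMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(c(1, 2, 3)))
#' nFaces(m)
#' @export
toothMesh <- function(vertices, faces, oriented = FALSE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(as.matrix(faces)), nrow = NROW(faces), ncol = 3)
  new("ToothMesh", vertices = vertices, faces = faces, oriented = oriented)
}

#' Lingual-view silhouette of a tooth crown
#'
#' The projection of an occlusally oriented crown onto the x-z plane
#' (x mesiodistal, z occlusal height), together with the cervical baseline
#' joining the mesial and distal cervical endpoints, the region heights
#' measured perpendicular to that baseline, and the maximal molar length
#' measured parallel to it.
#'
#' @slot points numeric k x 2 matrix of all projected vertices (x, z).
#' @slot outline numeric matrix; boundary polygon of the projection (closed,
#'   first row not repeated).
#' @slot baseline numeric 2 x 2 matrix; rows are the mesial and distal
#'   cervical endpoints in (x, z).
#' @slot splitFraction numeric in (0, 1); position of the trigonid/talonid
#'   division along the baseline, measured from the distal endpoint.
#' @slot hTri,hTal numeric; maximum trigonid / talonid heights perpendicular
#'   to the baseline.
#' @slot lMax numeric; maximum molar length parallel to the baseline.
#' @seealso [lingualSilhouette()], [computeTriTaHI()]
#' @export
setClass("Silhouette2D",
  representation(points = "matrix", outline = "matrix", baseline = "matrix",
                 splitFraction = "numeric", hTri = "numeric", hTal = "numeric",
                 lMax = "numeric"))

setValidity("Silhouette2D", function(object) {
  msgs <- character(0)
  if (ncol(object@points) != 2) msgs <- c(msgs, "points must be k x 2")
  if (!all(dim(object@baseline) == c(2, 2))) msgs <- c(msgs, "baseline must be 2 x 2")
  if (object@splitFraction <= 0 || object@splitFraction >= 1)
    msgs <- c(msgs, "splitFraction must lie strictly in (0, 1)")
  if (length(object@lMax) == 1 && is.finite(object@lMax) && object@lMax <= 0)
    msgs <- c(msgs, "lMax must be positive")
  if (length(msgs)) msgs else TRUE
})

#' One tooth's vector of dental topographic metrics
#'
#' Holds the eight crown-shape metrics for one tooth, plus failure tags for
#' any metric whose computation errored (the value is then `NA` and the tag
#' records the message).
#'
#' @slot metrics named numeric vector with entries `rfi`, `dne`, `convexDNE`,
#'   `ariaDNE`, `ariaDNE_CV`, `opcr`, `lnOA`, `tritahi`.
#' @slot failures named character vector of per-metric error messages.
#' @seealso [measureProfile()]
#' @export
setClass("TopographyProfile",
  representation(metrics = "numeric", failures = "character"))

.PROFILE_METRICS <- c("rfi", "dne", "convexDNE", "ariaDNE", "ariaDNE_CV",
                      "opcr", "lnOA", "tritahi")

setValidity("TopographyProfile", function(object) {
  if (!all(.PROFILE_METRICS %in% names(object@metrics)))
    return("metrics must contain all eight named entries")
  TRUE
})

#' Per-class Gaussian state of a quadratic discriminant diet classifier
#'
#' @slot classes character; ordered (lexicographic) diet labels.
#' @slot means numeric K x p matrix of class mean vectors.
#' @slot covariances list of p x p unbiased class covariance matrices.
#' @slot priors numeric; prior probability per class (sums to one; equal-prior
#'   mode sets each to 1/K exactly).
#' @slot features character; feature (metric) names, in model column order.
#' @seealso [qdaFit()], [qdaPredict()]
#' @export
setClass("DietModel",
  representation(classes = "character", means = "matrix",
                 covariances = "list", priors = "numeric",
                 features = "character"))

setValidity("DietModel", function(object) {
  msgs <- character(0)
  K <- length(object@classes)
  if (nrow(object@means) != K) msgs <- c(msgs, "means must have one row per class")
  if (length(object@covariances) != K) msgs <- c(msgs, "one covariance per class required")
  if (abs(sum(object@priors) - 1) > 1e-8) msgs <- c(msgs, "priors must sum to 1")
  for (k in seq_len(K)) {
    S <- object@covariances[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
      msgs <- c(msgs, sprintf("covariance of class '%s' is not symmetric", object@classes[k]))
      break
    }
    ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values, error = function(e) NA)
    if (anyNA(ev) || min(ev) <= 0) {
      msgs <- c(msgs, sprintf("covariance of class '%s' is not positive definite", object@classes[k]))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})
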