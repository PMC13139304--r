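#' @name mesh-accessors
#' @title Accessors for ToothMesh objects
#' @param x a [ToothMesh-class].
#' @return `meshVertices` / `meshFaces` return the coordinate / index
#'   matrices; `nVertices` / `nFaces` their row counts; `isOriented` the
#'   occlusal-orientation flag; `surfaceArea` the total 3D surface area.
NULL

#' @rdname mesh-accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname mesh-accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname mesh-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname mesh-accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname mesh-accessors
#' @export
setGeneric("isOriented", function(x) standardGeneric("isOriented"))
#' @rdname mesh-accessors
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' @rdname mesh-accessors
setMethod("meshVertices", "ToothMesh", function(x) x@vertices)
#' @rdname mesh-accessors
setMethod("meshFaces", "ToothMesh", function(x) x@faces)
#' @rdname mesh-accessors
setMethod("nVertices", "ToothMesh", function(x) nrow(x@vertices))
#' @rdname mesh-accessors
setMethod("nFaces", "ToothMesh", function(x) nrow(x@faces))
#' @rdname mesh-accessors
setMethod("isOriented", "ToothMesh", function(x) x@oriented)
#' @rdname mesh-accessors
setMethod("surfaceArea", "ToothMesh",
          function(x) sum(.faceAreas(x@vertices, x@faces)))

setMethod("show", "ToothMesh", function(object) {
  cat(sprintf("ToothMesh: %d vertices, %d faces%s\n",
              nrow(object@vertices), nrow(object@faces),
              if (object@oriented) " (occlusally oriented)" else ""))
  if (nrow(object@vertices)) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bbox: x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(object)
})

setMethod("show", "Silhouette2D", function(object) {
  cat(sprintf(paste0("Silhouette2D: %d projected points, %d outline vertices\n",
                     "  H_tri = %.4g, H_tal = %.4g, L_max = %.4g, split = %.2f\n"),
              nrow(object@points), nrow(object@outline),
              object@hTri, object@hTal, object@lMax, object@splitFraction))
  invisible(object)
})

setMethod("show", "TopographyProfile", function(object) {
  cat("TopographyProfile\n")
  m <- object@metrics
  for (nm in names(m)) {
    cat(sprintf("  %-10s %s\n", nm,
                if (is.na(m[[nm]]) && nm %in% names(object@failures))
                  paste0("<failed: ", object@failures[[nm]], ">")
                else format(m[[nm]], digits = 5)))
  }
  invisible(object)
})

setMethod("show", "DietModel", function(object) {
  cat(sprintf("DietModel: %d classes, %d features (%s)\n",
              length(object@classes), length(object@features),
              paste(object@features, collapse = ", ")))
  cat(sprintf("  classes: %s\n", paste(object@classes, collapse = ", ")))
  cat(sprintf("  priors:  %s\n",
              paste(format(object@priors, digits = 3), collapse = ", ")))
  invisible(object)
})

#' Metric values of a TopographyProfile
#'
#' @param x a [TopographyProfile-class].
#' @return Named numeric vector of the eight metrics (NA where a metric
#'   failed or was not requested).
#' @export
setGeneric("profileMetrics", function(x) standardGeneric("profileMetrics"))
#' @rdname profileMetrics
setMethod("profileMetrics", "TopographyProfile", function(x) x@metrics)
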