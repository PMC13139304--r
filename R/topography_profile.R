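#' Measure the full topographic profile of a tooth
#'
#' Computes RFI, DNE, convex DNE, ariaDNE, ariaDNE CV, OPCR and lnOA (the
#' natural log of the 2D occlusal outline area) on a preprocessed, occlusally
#' oriented mesh, plus TriTaHI when a silhouette is requested. Individual
#' metric failures do not abort the profile: the failing metric is set to
#' `NA` and tagged with its error message.
#'
#' @param mesh an occlusally oriented [ToothMesh-class].
#' @param metrics character; which metrics to compute (default all).
#' @param epsilon ariaDNE bandwidth (see [computeAriaDNE()]).
#' @param alpha outline alpha parameter (see [outlineArea()]).
#' @param boundary_exclude,outlier_fraction DNE options (see [computeDNE()]).
#' @param opcr_params named list of overrides for [computeOPCR()].
#' @param silhouette optional [Silhouette2D-class]; if absent and `"tritahi"`
#'   is requested, one is derived from the mesh with default settings.
#' @param split_fraction trigonid/talonid division for TriTaHI.
#' @return A [TopographyProfile-class].
#' @export
measureProfile <- function(mesh,
                           metrics = c("rfi", "dne", "convexDNE", "ariaDNE",
                                       "ariaDNE_CV", "opcr", "lnOA", "tritahi"),
                           epsilon = 0.08, alpha = "auto",
                           boundary_exclude = TRUE, outlier_fraction = 0.001,
                           opcr_params = list(), silhouette = NULL,
                           split_fraction = 0.5) {
  validObject(mesh)
  metrics <- match.arg(metrics, several.ok = TRUE)
  vals <- setNames(rep(NA_real_, length(.PROFILE_METRICS)), .PROFILE_METRICS)
  fails <- character(0)
  grab <- function(name, expr) {
    if (!name %in% metrics) return()
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) fails[[name]] <<- conditionMessage(res)
    else vals[[name]] <<- res
  }
  oa <- NULL
  if (any(c("lnOA", "rfi") %in% metrics)) {
    oaRes <- tryCatch(outlineArea(mesh, alpha = alpha), error = function(e) e)
    if (inherits(oaRes, "error")) {
      for (nm in intersect(c("lnOA", "rfi"), metrics))
        fails[[nm]] <- conditionMessage(oaRes)
    } else oa <- oaRes
  }
  if (!is.null(oa)) {
    if ("lnOA" %in% metrics) vals[["lnOA"]] <- log(oa)
    grab("rfi", {
      if (oa <= 0) stop("degenerate outline: zero outline area")
      log(sqrt(surfaceArea(mesh)) / sqrt(oa))
    })
  }
  dneRes <- NULL
  if (any(c("dne", "convexDNE") %in% metrics)) {
    dneRes <- tryCatch(
      computeDNE(mesh, boundary_exclude = boundary_exclude,
                 outlier_fraction = outlier_fraction, variant = "total"),
      error = function(e) e)
    if (inherits(dneRes, "error")) {
      for (nm in intersect(c("dne", "convexDNE"), metrics))
        fails[[nm]] <- conditionMessage(dneRes)
      dneRes <- NULL
    }
  }
  if (!is.null(dneRes)) {
    if ("dne" %in% metrics) vals[["dne"]] <- dneRes$dne
    if ("convexDNE" %in% metrics) {
      fld <- dneRes$field
      inc <- !fld$excluded & fld$convex
      vals[["convexDNE"]] <- sum(fld$energy[inc] * fld$area[inc])
    }
  }
  if (any(c("ariaDNE", "ariaDNE_CV") %in% metrics)) {
    ar <- tryCatch(computeAriaDNE(mesh, epsilon = epsilon), error = function(e) e)
    if (inherits(ar, "error")) {
      for (nm in intersect(c("ariaDNE", "ariaDNE_CV"), metrics))
        fails[[nm]] <- conditionMessage(ar)
    } else {
      if ("ariaDNE" %in% metrics) vals[["ariaDNE"]] <- ar$ariaDNE
      if ("ariaDNE_CV" %in% metrics) vals[["ariaDNE_CV"]] <- ar$ariaDNE_CV
    }
  }
  grab("opcr", as.numeric(do.call(computeOPCR, c(list(mesh), opcr_params))))
  grab("tritahi", {
    sil <- if (is.null(silhouette))
      lingualSilhouette(mesh, split_fraction = split_fraction) else silhouette
    computeTriTaHI(sil)
  })
  new("TopographyProfile", metrics = vals, failures = fails)
}
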