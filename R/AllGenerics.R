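#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("imageOrigin", function(x) standardGeneric("imageOrigin"))

#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' @export
setGeneric("crownAreas", function(x) standardGeneric("crownAreas"))

#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @export
setGeneric("crownOutlines", function(x) standardGeneric("crownOutlines"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("seEstimate", function(x) standardGeneric("seEstimate"))

#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @export
setGeneric("classEdges", function(x) standardGeneric("classEdges"))

#' @export
setGeneric("yieldFeatures", function(x) standardGeneric("yieldFeatures"))

#' Accessors for Orthoimage
#'
#' `pixelSize()` returns the ground sample distance (m/pixel),
#' `imageOrigin()` the world coordinates of the top-left pixel corner and
#' `imageArray()` the raw `H x W x 3` integer array.
#'
#' @param x an `Orthoimage`.
#' @name Orthoimage-accessors
#' @aliases pixelSize imageOrigin imageArray
NULL

#' @export
setMethod("pixelSize", "Orthoimage", function(x) x@pixelSize)
#' @export
setMethod("imageOrigin", "Orthoimage", function(x) x@origin)
#' @export
setMethod("imageArray", "Orthoimage", function(x) x@pixels)
#' @export
setMethod("dim", "Orthoimage", function(x) dim(x@pixels))

#' @export
setMethod("show", "Orthoimage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Orthoimage: %d x %d px, %.4g m/px (%.1f x %.1f m)\n",
              d[1], d[2], object@pixelSize,
              d[2] * object@pixelSize, d[1] * object@pixelSize))
  cat(sprintf("  origin (top-left corner): (%.2f, %.2f) m%s\n",
              object@origin[1], object@origin[2],
              if (is.na(object@crsLabel)) "" else paste0(" [", object@crsLabel, "]")))
})

#' Accessors for CrownRegionSet
#'
#' `regionTable()` returns the per-region data.frame, `crownAreas()` the
#' vector of crown areas in m2, `crownOutlines()` the list of boundary rings
#' and `pixelSize()` the ground sample distance used. `length()` gives the
#' number of regions.
#'
#' @param x a `CrownRegionSet`.
#' @name CrownRegionSet-accessors
#' @aliases crownAreas regionTable crownOutlines
NULL

#' @export
setMethod("regionTable", "CrownRegionSet", function(x) x@regions)
#' @export
setMethod("crownAreas", "CrownRegionSet", function(x) x@regions$area)
#' @export
setMethod("crownOutlines", "CrownRegionSet", function(x) x@outlines)
#' @export
setMethod("pixelSize", "CrownRegionSet", function(x) x@pixelSize)
#' @export
setMethod("length", "CrownRegionSet", function(x) nrow(x@regions))

#' @export
setMethod("show", "CrownRegionSet", function(object) {
  n <- nrow(object@regions)
  cat(sprintf("CrownRegionSet: %d region%s at %.4g m/px\n",
              n, if (n == 1) "" else "s", object@pixelSize))
  if (n > 0)
    cat(sprintf("  areas: %.2f - %.2f m2 (total %.1f m2)\n",
                min(object@regions$area), max(object@regions$area),
                sum(object@regions$area)))
})

#' Accessors for LinearModel
#'
#' `coef()` returns `c(intercept, slope)`; `rSquared()`, `seEstimate()` and
#' `nObs()` return the fit diagnostics (reported metadata for published
#' models). `confint()` gives t-based confidence intervals for fitted
#' models.
#'
#' @param x,object a `LinearModel`.
#' @name LinearModel-accessors
#' @aliases rSquared seEstimate nObs
NULL

#' @export
setMethod("coef", "LinearModel",
          function(object) c(intercept = object@intercept, slope = object@slope))
#' @export
setMethod("rSquared", "LinearModel", function(x) x@r2)
#' @export
setMethod("seEstimate", "LinearModel", function(x) x@seEstimate)
#' @export
setMethod("nObs", "LinearModel", function(x) x@n)

#' @export
setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel (%s): %s = %.4g %s %.4g * %s\n",
              object@source, object@responseLabel, object@intercept,
              if (object@slope < 0) "-" else "+", abs(object@slope),
              object@predictorLabel))
  cat(sprintf("  r2 = %.3g, SE of estimate = %.4g, n = %s\n",
              object@r2, object@seEstimate,
              if (is.na(object@n)) "NA" else object@n))
})

#' @export
setMethod("show", "OrchardSpec", function(object) {
  cat(sprintf("OrchardSpec: %s %s, %g x %g m spacing (%s) on %g x %g m\n",
              object@regime, object@category, object@spacing[1],
              object@spacing[2], object@layout,
              object@fieldSize[1], object@fieldSize[2]))
  cat(sprintf("  MCV %.1f +/- %.1f m3, canopy height %.1f +/- %.1f m, residual SD %.1f kg\n",
              object@mcvMean, object@mcvSd, object@canopyHeightMean,
              object@canopyHeightSd, object@residualSd))
})

#' Accessors for YieldMap
#'
#' `yieldFeatures()` returns the per-tree feature table and `classEdges()`
#' the yield class bin edges (kg/tree).
#'
#' @param x a `YieldMap`.
#' @name YieldMap-accessors
#' @aliases classEdges yieldFeatures
NULL

#' @export
setMethod("yieldFeatures", "YieldMap", function(x) x@features)
#' @export
setMethod("classEdges", "YieldMap", function(x) x@classEdges)
#' @export
setMethod("length", "YieldMap", function(x) nrow(x@features))

#' @export
setMethod("show", "YieldMap", function(object) {
  cat(sprintf("YieldMap (%s): %d trees, %d classes, OAY estimate %.0f kg/ha over %.2f ha\n",
              object@regime, nrow(object@features),
              length(object@classEdges) - 1L, object@totalOAY,
              object@footprintHa))
})
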