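#' Orthoimage: an RGB raster with a ground scale
#'
#' Container for a geometrically corrected aerial image. The pixel array is
#' `H x W x 3` integer with channel values in `[0, 255]`. `pixelSize` is the
#' ground sample distance in m/pixel (isotropic); `origin` holds the world
#' coordinates (m) of the top-left pixel corner, with x increasing east and
#' y increasing north (so image rows run from high y to low y).
#'
#' @slot pixels integer array, `H x W x 3`, values 0-255.
#' @slot pixelSize numeric(1), m/pixel, > 0.
#' @slot origin numeric(2), world (x, y) of the top-left pixel corner, m.
#' @slot crsLabel optional free-text tag for the coordinate system.
#' @exportClass Orthoimage
setClass("Orthoimage",
         representation(pixels = "array", pixelSize = "numeric",
                        origin = "numeric", crsLabel = "character"),
         prototype(origin = c(0, 0), crsLabel = NA_character_))

setValidity("Orthoimage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) return("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) return("image must have at least one pixel")
  rng <- range(object@pixels)
  if (anyNA(rng) || rng[1] < 0 || rng[2] > 255)
    return("channel values must lie in [0, 255]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single value > 0")
  if (length(object@origin) != 2L || anyNA(object@origin))
    return("origin must be numeric(2)")
  TRUE
})

#' CrownRegionSet: labelled tree crowns from a segmented orthoimage
#'
#' One row per connected canopy region ("particle"): label, pixel count,
#' area in m2, world centroid and bounding box. `outlines` holds one closed,
#' counter-clockwise pixel-edge boundary polygon (world coordinates) per
#' region, in label order.
#'
#' @slot regions data.frame with columns label, pixelCount, area, centroidX,
#'   centroidY, xmin, ymin, xmax, ymax.
#' @slot outlines list of two-column matrices (x, y), closed rings.
#' @slot pixelSize numeric(1), m/pixel the areas were computed at.
#' @slot maskDim integer(2), rows and columns of the source mask.
#' @slot origin numeric(2), world (x, y) of the mask's top-left corner.
#' @exportClass CrownRegionSet
setClass("CrownRegionSet",
         representation(regions = "data.frame", outlines = "list",
                        pixelSize = "numeric", maskDim = "integer",
                        origin = "numeric"))

setValidity("CrownRegionSet", function(object) {
  need <- c("label", "pixelCount", "area", "centroidX", "centroidY",
            "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(object@regions)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  r <- object@regions
  if (nrow(r) > 0) {
    if (any(r$label != seq_len(nrow(r)))) return("labels must be 1..n in order")
    if (max(abs(r$area - r$pixelCount * object@pixelSize^2)) > 1e-9)
      return("area must equal pixelCount * pixelSize^2")
    if (any(r$centroidX < r$xmin - 1e-9 | r$centroidX > r$xmax + 1e-9 |
            r$centroidY < r$ymin - 1e-9 | r$centroidY > r$ymax + 1e-9))
      return("centroid must lie inside the bounding box")
  }
  if (length(object@outlines) &&
      length(object@outlines) != nrow(r)) return("one outline per region")
  TRUE
})

#' LinearModel: a simple linear forecast y = a + b x
#'
#' Holds the coefficients of a single-predictor linear model along with fit
#' diagnostics: coefficient of determination, standard error of the estimate
#' (response units), coefficient standard errors (fitted models only), the
#' number of observations and the predictor range seen at fit time.
#' Published forecast equations carry their reported r2 and standard errors
#' as metadata (`source == "published"`); those diagnostics are not
#' recomputable without the original field data.
#'
#' @slot intercept,slope numeric(1) coefficients.
#' @slot r2 numeric(1) in [0, 1].
#' @slot seEstimate numeric(1), standard error of the estimate, >= 0.
#' @slot slopeSE,interceptSE numeric(1), NA for published models.
#' @slot n integer(1), observations (NA where unreported).
#' @slot predictorLabel,responseLabel character(1).
#' @slot validRange numeric(2), predictor range at fit time (may be NA).
#' @slot source `"fitted"` or `"published"`.
#' @exportClass LinearModel
setClass("LinearModel",
         representation(intercept = "numeric", slope = "numeric",
                        r2 = "numeric", seEstimate = "numeric",
                        slopeSE = "numeric", interceptSE = "numeric",
                        n = "integer", predictorLabel = "character",
                        responseLabel = "character", validRange = "numeric",
                        source = "character"),
         prototype(slopeSE = NA_real_, interceptSE = NA_real_,
                   n = NA_integer_, predictorLabel = "x", responseLabel = "y",
                   validRange = c(NA_real_, NA_real_), source = "fitted"))

setValidity("LinearModel", function(object) {
  for (s in c("intercept", "slope", "r2", "seEstimate"))
    if (length(slot(object, s)) != 1L) return(paste(s, "must be length 1"))
  if (!is.na(object@r2) && (object@r2 < -1e-12 || object@r2 > 1 + 1e-12))
    return("r2 must lie in [0, 1]")
  if (!is.na(object@seEstimate) && object@seEstimate < 0)
    return("seEstimate must be >= 0")
  if (!object@source %in% c("fitted", "published"))
    return("source must be 'fitted' or 'published'")
  if (object@source == "fitted" && (is.na(object@n) || object@n < 3L))
    return("fitted models need n >= 3")
  TRUE
})

#' OrchardSpec: parameters driving the synthetic orchard generator
#'
#' Describes an orchard layout (planting spacing, field size, grid or
#' quincunx rows) and the tree population to draw: truncated-normal manual
#' canopy volume and canopy height, plus the residual spread of yield about
#' the regime's forecast line. Defaults follow the reported populations of
#' common southern-Spain orchard categories; see the package vignette.
#'
#' @slot spacing numeric(2), in-row x between-row tree spacing, m.
#' @slot fieldSize numeric(2), field width and height, m.
#' @slot regime `"irrigated"` or `"rainfed"`.
#' @slot category `"traditional"`, `"intensive"` or `"large_hedgerow"`.
#' @slot layout `"grid"` or `"quincunx"` (offset rows).
#' @slot mcvMean,mcvSd canopy volume population, m3/tree.
#' @slot canopyHeightMean,canopyHeightSd vertical crown axis, m.
#' @slot residualSd yield residual SD about the forecast line, kg/tree.
#' @slot pixelSize rendering ground sample distance, m/pixel.
#' @slot eccentricity crown diameter ratio d1/d2 (1 = circular crowns).
#' @slot sunVector numeric(2), world offset of the shadow ellipse, m.
#' @slot seed RNG seed (NA = use the current RNG state).
#' @exportClass OrchardSpec
setClass("OrchardSpec",
         representation(spacing = "numeric", fieldSize = "numeric",
                        regime = "character", category = "character",
                        layout = "character", mcvMean = "numeric",
                        mcvSd = "numeric", canopyHeightMean = "numeric",
                        canopyHeightSd = "numeric", residualSd = "numeric",
                        pixelSize = "numeric", eccentricity = "numeric",
                        sunVector = "numeric", seed = "numeric"))

setValidity("OrchardSpec", function(object) {
  if (any(object@spacing <= 0) || length(object@spacing) != 2L)
    return("spacing must be two positive lengths")
  if (any(object@fieldSize <= 0) || length(object@fieldSize) != 2L)
    return("fieldSize must be two positive lengths")
  if (!object@regime %in% c("irrigated", "rainfed"))
    return("regime must be 'irrigated' or 'rainfed'")
  if (!object@category %in% c("traditional", "intensive", "large_hedgerow"))
    return("unknown orchard category")
  if (!object@layout %in% c("grid", "quincunx"))
    return("layout must be 'grid' or 'quincunx'")
  if (object@mcvSd < 0 || object@canopyHeightSd < 0 || object@residualSd < 0)
    return("standard deviations must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@eccentricity <= 0) return("eccentricity must be > 0")
  TRUE
})

#' YieldMap: per-tree forecast yield attached to crown outlines
#'
#' The thematic-map object: one feature per delineated crown carrying its
#' area (ICA, m2), the canopy volume estimate chained through the published
#' area-to-volume model, the forecast yield (kg/tree) and a discrete class
#' index. `classEdges` are the yield bin edges; `totalOAY` is the summed
#' forecast divided by the mapped footprint in hectares (kg/ha).
#'
#' @slot features data.frame: label, centroidX, centroidY, ica, mcvEst,
#'   ayForecast, classIndex.
#' @slot outlines list of closed rings, parallel to features.
#' @slot classEdges numeric yield bin edges, kg/tree.
#' @slot regime regime used for the forecast.
#' @slot totalOAY numeric(1), kg/ha over the mapped footprint.
#' @slot footprintHa numeric(1), mapped area, ha.
#' @exportClass YieldMap
setClass("YieldMap",
         representation(features = "data.frame", outlines = "list",
                        classEdges = "numeric", regime = "character",
                        totalOAY = "numeric", footprintHa = "numeric"))

setValidity("YieldMap", function(object) {
  f <- object@features
  need <- c("label", "centroidX", "centroidY", "ica", "mcvEst",
            "ayForecast", "classIndex")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  k <- length(object@classEdges) - 1L
  if (nrow(f) > 0 && (any(f$classIndex < 1L) || any(f$classIndex > k)))
    return("classIndex must index into classEdges bins")
  TRUE
})
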