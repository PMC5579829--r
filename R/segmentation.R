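#' Segmentation parameters for crown delineation
#'
#' Bundles the dual thresholds and particle-analysis settings. A pixel is
#' canopy iff its working-channel value `v` satisfies
#' `shadowThreshold < v <= groundThreshold`: soil is brighter than canopy in
#' the working channel (removed by the upper, "ground" threshold) and
#' shadows are darker (removed by the lower, "shadow" threshold). The
#' half-open band convention is fixed and covered by tests.
#'
#' @param groundThreshold upper cutoff, 0-255; values above are soil.
#' @param shadowThreshold lower cutoff, 0-255; values at or below are shadow.
#' @param channel working channel, `"green"` (default) or `"lightness"`.
#' @param minArea smallest particle kept, m2 (default 1 m2, suppressing
#'   weed/noise speckle).
#' @param maxArea areas above this trigger a merged-crown warning, m2.
#' @param connectivity pixel adjacency for labelling, 4 or 8 (default 8).
#' @return a `segmentationParams` list.
#' @export
segmentationParams <- function(groundThreshold, shadowThreshold,
                               channel = c("green", "lightness"),
                               minArea = 1.0, maxArea = Inf,
                               connectivity = 8L) {
  channel <- match.arg(channel)
  assertNumeric(groundThreshold, "groundThreshold", nonneg = TRUE)
  assertNumeric(shadowThreshold, "shadowThreshold", nonneg = TRUE)
  if (groundThreshold > 255 || shadowThreshold > 255)
    validationError("thresholds must lie in [0, 255]")
  if (shadowThreshold >= groundThreshold)
    validationError("shadowThreshold must be below groundThreshold (empty band)")
  if (minArea < 0) validationError("minArea must be >= 0")
  if (!connectivity %in% c(4L, 8L))
    validationError("connectivity must be 4 or 8")
  structure(list(groundThreshold = groundThreshold,
                 shadowThreshold = shadowThreshold, channel = channel,
                 minArea = minArea, maxArea = maxArea,
                 connectivity = as.integer(connectivity)),
            class = "segmentationParams")
}

#' Dual-threshold canopy segmentation
#'
#' Binarises the working channel with the band rule of
#' [segmentationParams()]: canopy pixels are those strictly above the shadow
#' threshold and at or below the ground threshold.
#'
#' @param img an [Orthoimage-class] (or an integer channel matrix).
#' @param params a [segmentationParams()] object.
#' @return logical `H x W` matrix, `TRUE` for canopy.
#' @export
segmentCanopy <- function(img, params) {
  stopifnot(inherits(params, "segmentationParams"))
  ch <- if (is.matrix(img)) img else extractChannel(img, params$channel)
  ch > params$shadowThreshold & ch <= params$groundThreshold
}

#' Otsu's threshold on an 8-bit histogram
#'
#' Exhaustive search over 0..255 for the cut `t` maximising the
#' between-class variance of the classes `v <= t` and `v > t`. Ties take the
#' lowest `t`. A constant input returns the constant with a warning.
#'
#' @param values integer vector or matrix of channel values in 0-255.
#' @return threshold in \[0, 255\].
#' @export
otsuThreshold <- function(values) {
  v <- as.vector(values)
  if (length(v) == 0L) validationError("empty raster")
  h <- as.numeric(tabulate(v + 1L, nbins = 256L))
  idx <- which(h > 0)
  if (length(idx) == 1L) {
    warning("constant raster: degenerate threshold")
    return(idx - 1L)
  }
  n <- sum(h)
  w <- cumsum(h)                    # count of v <= t, t = 0..255
  m <- cumsum(h * (0:255))          # sum of values <= t
  mt <- m[256]
  valid <- w > 0 & w < n
  bcv <- rep(-Inf, 256)
  bcv[valid] <- (mt * w[valid] - n * m[valid])^2 / (w[valid] * (n - w[valid]))
  which.max(bcv) - 1L
}

#' Suggest ground and shadow thresholds automatically
#'
#' An automation aid for the manual threshold choice: the ground threshold
#' is Otsu's cut over the whole channel (separating bright soil from the
#' rest), and the shadow threshold is Otsu applied to the sub-histogram at
#' or below the ground cut (separating dark shadow from canopy).
#'
#' @param channelRaster integer matrix of channel values 0-255.
#' @return list with `ground` and `shadow` thresholds.
#' @export
suggestThresholds <- function(channelRaster) {
  ground <- otsuThreshold(channelRaster)
  sub <- channelRaster[channelRaster <= ground]
  shadow <- if (length(sub)) otsuThreshold(sub) else ground
  list(ground = as.numeric(ground), shadow = as.numeric(shadow))
}
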