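#' Construct an Orthoimage
#'
#' @param pixels `H x W x 3` numeric/integer array with values in 0-255, or
#'   in 0-1 (as returned by [png::readPNG]), which is rescaled.
#' @param pixelSize ground sample distance, m/pixel.
#' @param origin world (x, y) of the top-left pixel corner, m.
#' @param crsLabel optional coordinate-system tag.
#' @return an [Orthoimage-class] object.
#' @export
Orthoimage <- function(pixels, pixelSize, origin = c(0, 0),
                       crsLabel = NA_character_) {
  assertNumeric(pixelSize, "pixelSize", positive = TRUE)
  if (length(dim(pixels)) == 3L && dim(pixels)[3] > 3L)
    pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
  if (length(pixels) && max(pixels) <= 1 && min(pixels) >= 0)
    pixels <- roundHalfUp(pixels * 255)
  storage.mode(pixels) <- "integer"
  methods::new("Orthoimage", pixels = pixels, pixelSize = pixelSize,
               origin = as.numeric(origin), crsLabel = crsLabel)
}

#' Convert a scale reference to a ground sample distance
#'
#' An object of known ground length measured in the image calibrates the
#' pixel size: `pixelSize = referenceLengthM / referenceLengthPx`.
#'
#' @param referenceLengthPx length of the reference in pixels, > 0.
#' @param referenceLengthM ground length of the reference, m, > 0.
#' @return pixel size, m/pixel.
#' @export
calibrateScale <- function(referenceLengthPx, referenceLengthM) {
  assertNumeric(referenceLengthPx, "referenceLengthPx", positive = TRUE)
  assertNumeric(referenceLengthM, "referenceLengthM", positive = TRUE)
  referenceLengthM / referenceLengthPx
}

#' Read an orthoimage from PNG or TIFF
#'
#' PNG is the primary format. The pixel size (and optionally the origin)
#' come either from the arguments or from a sidecar JSON file
#' (`<image>.json`, fields `pixel_size`, `origin`) as written by
#' [writeOrthoimage()]. TIFF rasters are read via the `tiff` package when
#' available; geo tags are not interpreted, so the scale must be supplied.
#'
#' @param path image path (`.png`, `.tif`/`.tiff`).
#' @param pixelSize m/pixel; overrides any sidecar value.
#' @param origin world (x, y) of the top-left corner; default from sidecar
#'   or `c(0, H * pixelSize)` so the bottom-left corner is (0, 0).
#' @return an [Orthoimage-class].
#' @export
readOrthoimage <- function(path, pixelSize = NULL, origin = NULL) {
  if (!file.exists(path)) ioError("image not found: %s", path)
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(pixelSize)) pixelSize <- meta$pixel_size
  if (is.null(pixelSize))
    validationError("no pixel size: pass pixelSize= or provide a sidecar JSON")
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      ioError("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else ioError("unsupported image format: .%s", ext)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (is.null(origin)) origin <- unlist(meta$origin)
  if (is.null(origin)) origin <- c(0, dim(px)[1] * pixelSize)
  Orthoimage(px, as.numeric(pixelSize), origin)
}

#' Write an orthoimage as PNG plus a sidecar JSON
#'
#' The sidecar (`<image>.json`) records `pixel_size`, `origin` and any extra
#' metadata (e.g. the generator seed), so [readOrthoimage()] can restore the
#' ground scale.
#'
#' @param img an [Orthoimage-class].
#' @param path output PNG path.
#' @param extra named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
writeOrthoimage <- function(img, path, extra = list()) {
  stopifnot(methods::is(img, "Orthoimage"))
  png::writePNG(img@pixels / 255, path)
  meta <- c(list(pixel_size = img@pixelSize, origin = img@origin), extra)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a working channel from an RGB orthoimage
#'
#' `"green"` returns the raw green band (the default segmentation channel);
#' `"lightness"` returns the HSL lightness grayscale,
#' `(max(R,G,B) + min(R,G,B)) / 2`, rounded half-up to an integer in 0-255.
#'
#' @param img an [Orthoimage-class].
#' @param channel one of `"green"`, `"lightness"`, `"red"`, `"blue"`.
#' @return integer matrix `H x W` with values 0-255.
#' @export
extractChannel <- function(img, channel = c("green", "lightness", "red", "blue")) {
  stopifnot(methods::is(img, "Orthoimage"))
  channel <- match.arg(channel)
  p <- img@pixels
  r <- p[, , 1, drop = FALSE]; g <- p[, , 2, drop = FALSE]
  b <- p[, , 3, drop = FALSE]
  out <- switch(channel,
    red = r, green = g, blue = b,
    lightness = roundHalfUp((pmax(r, g, b) + pmin(r, g, b)) / 2))
  dim(out) <- dim(p)[1:2]
  storage.mode(out) <- "integer"
  out
}

#' @rdname extractChannel
#' @export
toLightness <- function(img) extractChannel(img, "lightness")
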