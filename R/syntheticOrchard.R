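#' Construct an orchard specification for the synthetic generator
#'
#' Default population parameters follow the reported means and SDs for the
#' three common southern-Spain orchard categories measured in on-years:
#' manual canopy volume 12.1 +/- 1.7 m3 (irrigated intensive),
#' 73.6 +/- 27.6 m3 (rainfed traditional), 98.0 +/- 9.9 m3 (irrigated
#' traditional); canopy height 3.8 +/- 0.2 m (irrigated) or 3.9 +/- 0.4 m
#' (rainfed); yield residual SD about the regime forecast line 13.1 kg/tree
#' (irrigated) or 17.1 kg/tree (rainfed). Other regime/category
#' combinations have no reported population and require explicit
#' `mcvMean`/`mcvSd`.
#'
#' @param spacing numeric(2): in-row and between-row spacing, m.
#' @param fieldSize numeric(2): field width (x) and height (y), m
#'   (default 100 x 100 m = 1 ha).
#' @param regime `"irrigated"` or `"rainfed"`.
#' @param category `"traditional"`, `"intensive"` or `"large_hedgerow"`.
#' @param layout `"grid"` or `"quincunx"` (alternate rows offset by half
#'   the in-row spacing).
#' @param mcvMean,mcvSd canopy volume population, m3.
#' @param canopyHeightMean,canopyHeightSd vertical crown axis, m.
#' @param residualSd yield residual SD, kg/tree.
#' @param pixelSize rendering scale, m/pixel (default 0.02).
#' @param eccentricity crown diameter ratio d1/d2 (default 1: circular).
#' @param sunVector world offset of shadows, m (default `c(1.5, -1.5)`).
#' @param seed RNG seed for [generateOrchard()] (NA = current RNG state).
#' @return an [OrchardSpec-class].
#' @export
orchardSpec <- function(spacing, fieldSize = c(100, 100),
                        regime = c("irrigated", "rainfed"),
                        category = c("traditional", "intensive", "large_hedgerow"),
                        layout = c("grid", "quincunx"),
                        mcvMean = NULL, mcvSd = NULL,
                        canopyHeightMean = NULL, canopyHeightSd = NULL,
                        residualSd = NULL, pixelSize = 0.02,
                        eccentricity = 1, sunVector = c(1.5, -1.5),
                        seed = NA_real_) {
  regime <- match.arg(regime)
  category <- match.arg(category)
  layout <- match.arg(layout)
  popDefaults <- list(
    irrigated.intensive   = c(mean = 12.1, sd = 1.7),
    rainfed.traditional   = c(mean = 73.6, sd = 27.6),
    irrigated.traditional = c(mean = 98.0, sd = 9.9))
  key <- paste(regime, category, sep = ".")
  if (is.null(mcvMean) || is.null(mcvSd)) {
    if (is.null(popDefaults[[key]]))
      validationError("no default canopy-volume population for %s %s: pass mcvMean and mcvSd",
                      regime, category)
    if (is.null(mcvMean)) mcvMean <- popDefaults[[key]]["mean"]
    if (is.null(mcvSd)) mcvSd <- popDefaults[[key]]["sd"]
  }
  if (is.null(canopyHeightMean))
    canopyHeightMean <- if (regime == "irrigated") 3.8 else 3.9
  if (is.null(canopyHeightSd))
    canopyHeightSd <- if (regime == "irrigated") 0.2 else 0.4
  if (is.null(residualSd))
    residualSd <- if (regime == "irrigated") 13.1 else 17.1
  methods::new("OrchardSpec", spacing = as.numeric(spacing),
               fieldSize = as.numeric(fieldSize), regime = regime,
               category = category, layout = layout,
               mcvMean = unname(as.numeric(mcvMean)),
               mcvSd = unname(as.numeric(mcvSd)),
               canopyHeightMean = as.numeric(canopyHeightMean),
               canopyHeightSd = as.numeric(canopyHeightSd),
               residualSd = as.numeric(residualSd),
               pixelSize = pixelSize, eccentricity = eccentricity,
               sunVector = as.numeric(sunVector), seed = as.numeric(seed))
}

#' Draw a synthetic tree population
#'
#' Per tree: canopy height from a truncated normal (> 0.5 m), manual canopy
#' volume from a truncated normal (> 1 m3), crown diameters solved from the
#' ellipsoid volume model given MCV and height
#' (`d1 d2 = 6 MCV / (pi h)`, split by the eccentricity ratio), crown area
#' `ICA = pi d1 d2 / 4`, and yield from the regime's published forecast
#' line plus Gaussian residual noise, truncated at zero. MCV and height are
#' drawn independently.
#'
#' @param n number of trees.
#' @param spec an [OrchardSpec-class].
#' @return data.frame: `true_mcv`, `true_ica`, `true_ay`, `d1`, `d2`,
#'   `canopy_height`.
#' @export
sampleTreePopulation <- function(n, spec) {
  stopifnot(methods::is(spec, "OrchardSpec"))
  if (n < 1L) validationError("need at least one tree")
  h <- rtruncnorm(n, spec@canopyHeightMean, spec@canopyHeightSd, 0.5)
  mcv <- rtruncnorm(n, spec@mcvMean, spec@mcvSd, 1)
  dProd <- 6 * mcv / (pi * h)                 # d1 * d2
  d1 <- sqrt(dProd * spec@eccentricity)
  d2 <- sqrt(dProd / spec@eccentricity)
  ica <- pi * d1 * d2 / 4
  ayLine <- forecastAYfromMCV(mcv, spec@regime)
  ay <- pmax(0, ayLine + stats::rnorm(n, 0, spec@residualSd))
  data.frame(true_mcv = mcv, true_ica = ica, true_ay = ay,
             d1 = d1, d2 = d2, canopy_height = h)
}

#' Generate a synthetic orchard
#'
#' Places trees on a rectangular grid (optionally quincunx: alternate rows
#' offset by half the in-row spacing) at the spec's spacing with a
#' half-spacing margin, then draws each tree's geometry and yield with
#' [sampleTreePopulation()]. The tree count is the planting density
#' `floor(10000 / (a b))` scaled to the field area, capped by the number of
#' grid positions that physically fit; positions are filled in raster
#' order. Deterministic for a fixed `seed` in the spec.
#'
#' @param spec an [OrchardSpec-class].
#' @return data.frame: `tree_id`, `x`, `y` (m, world coordinates with the
#'   field's south-west corner at the origin), plus the columns of
#'   [sampleTreePopulation()].
#' @export
generateOrchard <- function(spec) {
  stopifnot(methods::is(spec, "OrchardSpec"))
  if (!is.na(spec@seed)) set.seed(spec@seed)
  a <- spec@spacing[1]; b <- spec@spacing[2]
  fw <- spec@fieldSize[1]; fh <- spec@fieldSize[2]
  if (a / 2 > fw || b / 2 > fh)
    validationError("field %g x %g m too small for one tree at %g x %g m spacing",
                    fw, fh, a, b)
  xs <- seq(a / 2, fw, by = a)
  ys <- seq(b / 2, fh, by = b)
  pos <- expand.grid(x = xs, y = ys)          # raster order, x fastest
  if (spec@layout == "quincunx") {
    off <- rep(c(0, a / 2), length.out = length(ys))[match(pos$y, ys)]
    pos$x <- pos$x + off
    pos <- pos[pos$x <= fw, ]
  }
  areaHa <- fw * fh / 10000
  nTarget <- floor(plantingDensity(a, b) * areaHa)
  n <- min(nrow(pos), max(1L, nTarget))
  pos <- pos[seq_len(n), ]
  trees <- sampleTreePopulation(n, spec)
  cbind(data.frame(tree_id = seq_len(n), x = pos$x, y = pos$y,
                   row.names = NULL), trees)
}

# palette the renderer uses; green-channel values are well separated
# (soil 172 > crown 96 > shadow 38) so the dual-threshold band isolates
# crowns
.renderPalette <- list(soil = c(196, 172, 120), crown = c(70, 96, 52),
                       shadow = c(38, 38, 38), noiseSd = 6)

#' Render an RGB orthoimage of a synthetic orchard
#'
#' Produces imagery with the intensity structure the segmentation stage
#' assumes: a bright soil background with additive Gaussian pixel noise,
#' each crown an axis-aligned filled ellipse (semi-axes d1/2, d2/2) in
#' crown green, and a dark shadow ellipse offset by the spec's sun vector
#' drawn beneath the crowns. Image dimensions are `fieldSize / pixelSize`
#' rounded up; the world origin is the field's south-west corner.
#' Overlapping crowns are allowed but counted in a warning (they merge into
#' single regions downstream).
#'
#' @param trees data.frame from [generateOrchard()].
#' @param spec the [OrchardSpec-class] used to generate them.
#' @return an [Orthoimage-class].
#' @export
renderOrthoimage <- function(trees, spec) {
  stopifnot(methods::is(spec, "OrchardSpec"))
  ps <- spec@pixelSize
  W <- as.integer(ceiling(spec@fieldSize[1] / ps))
  H <- as.integer(ceiling(spec@fieldSize[2] / ps))
  if (nrow(trees) > 0 &&
      (any(trees$x < 0 | trees$x > spec@fieldSize[1]) ||
       any(trees$y < 0 | trees$y > spec@fieldSize[2])))
    validationError("trees outside the field bounds")
  pal <- .renderPalette
  y0 <- H * ps  # world y of the top edge
  # pixel (row, col) indices whose centre lies inside an ellipse
  ellipsePixels <- function(cx, cy, sa, sb) {
    jlo <- max(1L, floor((cx - sa) / ps)); jhi <- min(W, ceiling((cx + sa) / ps) + 1L)
    ilo <- max(1L, floor((y0 - cy - sb) / ps)); ihi <- min(H, ceiling((y0 - cy + sb) / ps) + 1L)
    if (jlo > jhi || ilo > ihi) return(NULL)
    jj <- jlo:jhi; ii <- ilo:ihi
    px <- (jj - 0.5) * ps; py <- y0 - (ii - 0.5) * ps
    inside <- outer(((py - cy) / sb)^2, ((px - cx) / sa)^2, "+") <= 1
    idx <- which(inside, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(NULL)
    cbind(ii[idx[, 1]], jj[idx[, 2]])
  }
  gather <- function(dx = 0, dy = 0) do.call(rbind, lapply(seq_len(nrow(trees)),
    function(i) ellipsePixels(trees$x[i] + dx, trees$y[i] + dy,
                              trees$d1[i] / 2, trees$d2[i] / 2)))
  sh <- cr <- NULL
  if (nrow(trees) > 0) {
    sv <- spec@sunVector
    if (any(sv != 0)) sh <- gather(sv[1], sv[2])
    cr <- gather()
    nOv <- countCrownOverlaps(trees)
    if (nOv > 0)
      warning(sprintf("%d overlapping crown pair(s): expect merged regions", nOv))
  }
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(pal$soil[ch], H, W)
    if (!is.null(sh)) plane[sh] <- pal$shadow[ch]
    if (!is.null(cr)) plane[cr] <- pal$crown[ch]
    img[, , ch] <- plane
  }
  img <- img + stats::rnorm(length(img), 0, pal$noiseSd)
  Orthoimage(roundHalfUp(pmin(pmax(img, 0), 255)), ps, origin = c(0, y0))
}

# pairs of crowns whose ellipses can intersect (conservative circle test on
# the larger semi-axis)
countCrownOverlaps <- function(trees) {
  n <- nrow(trees)
  if (n < 2L) return(0L)
  rad <- pmax(trees$d1, trees$d2) / 2
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    d <- sqrt((trees$x[-seq_len(i)] - trees$x[i])^2 +
              (trees$y[-seq_len(i)] - trees$y[i])^2)
    cnt <- cnt + sum(d < rad[i] + rad[-seq_len(i)])
  }
  cnt
}

#' Write or read a ground-truth tree table
#'
#' CSV columns `tree_id,x,y,true_mcv,true_ica,true_ay,d1,d2,canopy_height`;
#' values round-trip losslessly at full double precision.
#'
#' @param trees data.frame from [generateOrchard()].
#' @param path file path.
#' @return `writeGroundTruth`: `path` invisibly; `readGroundTruth`: the table.
#' @export
writeGroundTruth <- function(trees, path) {
  need <- c("tree_id", "x", "y", "true_mcv", "true_ica", "true_ay",
            "d1", "d2", "canopy_height")
  if (nrow(trees) == 0L) validationError("empty tree list")
  if (!all(need %in% names(trees)))
    validationError("tree table must have columns: %s", paste(need, collapse = ","))
  ok <- tryCatch({
    utils::write.csv(trees[need], path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) ioError("cannot write ground truth to %s: %s",
                           path, conditionMessage(ok))
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path)) ioError("ground-truth table not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
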