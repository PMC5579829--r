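#' Label connected canopy regions ("analyze particles")
#'
#' Connected-component labelling of a binary canopy mask, with per-region
#' pixel counts, areas in m2, world centroids, bounding boxes and pixel-edge
#' outline polygons. Components are found by run-length encoding each image
#' row and merging vertically adjacent runs with union-find; labels are
#' assigned in raster-scan order of each component's first pixel, starting
#' at 1. Components smaller than `minArea` are discarded; components larger
#' than `maxArea` are kept but flagged with a merged-crown warning (touching
#' crowns are not split). Outlines are the outer boundary ring (largest
#' enclosed area); for hole-free regions — tree crowns in practice — the
#' ring encloses exactly `pixelCount` pixels, while regions with interior
#' holes enclose more.
#'
#' @param mask logical `H x W` matrix, `TRUE` for canopy.
#' @param pixelSize ground sample distance, m/pixel.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent,
#'   the particle-analysis default).
#' @param minArea discard threshold, m2 (default 0 here; the pipeline
#'   default of 1 m2 comes from [segmentationParams()]).
#' @param maxArea merged-crown warning threshold, m2.
#' @param origin world (x, y) of the mask's top-left corner; default puts
#'   the bottom-left corner at (0, 0).
#' @param outlines compute boundary polygons (set `FALSE` to skip).
#' @return a [CrownRegionSet-class].
#' @export
labelRegions <- function(mask, pixelSize, connectivity = 8L, minArea = 0,
                         maxArea = Inf, origin = NULL, outlines = TRUE) {
  if (!is.matrix(mask) || !is.logical(mask))
    validationError("mask must be a logical matrix")
  assertNumeric(pixelSize, "pixelSize", positive = TRUE)
  if (!connectivity %in% c(4L, 8L)) validationError("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(origin)) origin <- c(0, H * pixelSize)
  emptySet <- function() methods::new("CrownRegionSet",
    regions = data.frame(label = integer(), pixelCount = integer(),
                         area = numeric(), centroidX = numeric(),
                         centroidY = numeric(), xmin = numeric(),
                         ymin = numeric(), xmax = numeric(), ymax = numeric()),
    outlines = list(), pixelSize = pixelSize, maskDim = c(H, W),
    origin = as.numeric(origin))
  if (!any(mask)) return(emptySet())

  rl <- runLabel(mask, connectivity)
  runRow <- rl$runRow; c1 <- rl$c1; c2 <- rl$c2; lab <- rl$lab
  k <- max(lab)
  labf <- factor(lab, levels = seq_len(k))

  len <- c2 - c1 + 1L
  pc <- as.vector(tapply(len, labf, sum))
  meanRow <- as.vector(tapply(len * runRow, labf, sum)) / pc
  meanCol <- as.vector(tapply(len * (c1 + c2) / 2, labf, sum)) / pc
  rmin <- as.vector(tapply(runRow, labf, min))
  rmax <- as.vector(tapply(runRow, labf, max))
  cmin <- as.vector(tapply(c1, labf, min))
  cmax <- as.vector(tapply(c2, labf, max))

  area <- pc * pixelSize^2
  keep <- which(area >= minArea)
  if (length(keep) == 0L) return(emptySet())
  if (any(area[keep] > maxArea))
    warning(sprintf("%d region(s) exceed maxArea = %g m2: possibly merged crowns",
                    sum(area[keep] > maxArea), maxArea))

  x0 <- origin[1]; y0 <- origin[2]
  regions <- data.frame(
    label = seq_along(keep),
    pixelCount = pc[keep],
    area = area[keep],
    centroidX = x0 + (meanCol[keep] - 0.5) * pixelSize,
    centroidY = y0 - (meanRow[keep] - 0.5) * pixelSize,
    xmin = x0 + (cmin[keep] - 1) * pixelSize,
    ymin = y0 - rmax[keep] * pixelSize,
    xmax = x0 + cmax[keep] * pixelSize,
    ymax = y0 - (rmin[keep] - 1) * pixelSize)

  outlineList <- list()
  if (outlines) {
    outlineList <- vector("list", length(keep))
    for (ii in seq_along(keep)) {
      lb <- keep[ii]
      runsOf <- which(lab == lb)
      sub <- matrix(FALSE, rmax[lb] - rmin[lb] + 1L, cmax[lb] - cmin[lb] + 1L)
      for (rn in runsOf)
        sub[runRow[rn] - rmin[lb] + 1L,
            (c1[rn]:c2[rn]) - cmin[lb] + 1L] <- TRUE
      ring <- traceOutline(sub)
      outlineList[[ii]] <- cbind(
        x = x0 + (cmin[lb] - 1 + ring[, 1]) * pixelSize,
        y = y0 - (rmin[lb] - 1 + ring[, 2]) * pixelSize)
    }
  }
  methods::new("CrownRegionSet", regions = regions, outlines = outlineList,
               pixelSize = pixelSize, maskDim = c(H, W),
               origin = as.numeric(origin))
}

# Row-major run-length encoding of a binary mask plus union-find merging of
# vertically adjacent runs (one-column tolerance under 8-connectivity).
# Returns runs (row, first col, last col) and their component label, with
# labels in raster-scan order of each component's first pixel.
runLabel <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  v <- as.vector(t(mask))
  N <- length(v)
  colpos <- rep.int(seq_len(W), H)
  isStart <- v & (colpos == 1L | !c(FALSE, v[-N]))
  isEnd   <- v & (colpos == W  | !c(v[-1], FALSE))
  starts <- which(isStart); ends <- which(isEnd)
  runRow <- (starts - 1L) %/% W + 1L
  c1 <- (starts - 1L) %% W + 1L
  c2 <- (ends - 1L) %% W + 1L
  nr <- length(starts)
  parent <- seq_len(nr)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[[parent[i]]]; i <- parent[i] }
    i
  }
  tol <- if (connectivity == 8L) 1L else 0L
  byRow <- split(seq_len(nr), runRow)
  rowsPresent <- as.integer(names(byRow))
  for (k in seq_along(rowsPresent)) {
    r <- rowsPresent[k]
    j <- match(r + 1L, rowsPresent)
    if (is.na(j)) next
    a <- byRow[[k]]; b <- byRow[[j]]
    ia <- 1L; ib <- 1L
    while (ia <= length(a) && ib <= length(b)) {
      ra <- a[ia]; rb <- b[ib]
      if (c2[ra] + tol < c1[rb]) { ia <- ia + 1L }
      else if (c2[rb] + tol < c1[ra]) { ib <- ib + 1L }
      else {
        pa <- findRoot(ra); pb <- findRoot(rb)
        if (pa != pb) parent[if (pa < pb) pb else pa] <- min(pa, pb)
        if (c2[ra] <= c2[rb]) ia <- ia + 1L else ib <- ib + 1L
      }
    }
  }
  comp <- vapply(seq_len(nr), findRoot, integer(1))
  list(runRow = runRow, c1 = c1, c2 = c2, lab = match(comp, unique(comp)))
}

#' Connected-component label matrix
#'
#' Lower-level companion of [labelRegions()]: returns the integer label of
#' every pixel (0 = background), with component labels assigned in
#' raster-scan order of each component's first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape.
#' @export
labelMask <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask) || !is.logical(mask))
    validationError("mask must be a logical matrix")
  if (!connectivity %in% c(4L, 8L)) validationError("connectivity must be 4 or 8")
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  rl <- runLabel(mask, connectivity)
  for (i in seq_along(rl$lab))
    out[rl$runRow[i], rl$c1[i]:rl$c2[i]] <- rl$lab[i]
  out
}

# Trace the outer pixel-edge boundary of a binary submask. Boundary edges
# are directed so the region interior lies to the left in world orientation
# (y up); chaining them yields counter-clockwise outer rings and clockwise
# hole rings. At pinch vertices (diagonal contacts) the sharpest right turn
# is taken, which keeps 8-connected diagonal neighbours on one ring. The
# ring with the largest signed area (the outer boundary) is returned as a
# closed two-column matrix of grid-corner coordinates (col, row).
traceOutline <- function(sub) {
  H <- nrow(sub); W <- ncol(sub)
  idx <- which(sub)
  r <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  at <- function(rr, ccc) rr >= 1L & rr <= H & ccc >= 1L & ccc <= W &
    sub[cbind(pmax(pmin(rr, H), 1L), pmax(pmin(ccc, W), 1L))]
  # edges as (from_col, from_row, to_col, to_row) in grid corners
  es <- list()
  top <- !at(r - 1L, cc)
  es[[1]] <- cbind(cc, r - 1L, cc - 1L, r - 1L)[top, , drop = FALSE]
  bot <- !at(r + 1L, cc)
  es[[2]] <- cbind(cc - 1L, r, cc, r)[bot, , drop = FALSE]
  lef <- !at(r, cc - 1L)
  es[[3]] <- cbind(cc - 1L, r - 1L, cc - 1L, r)[lef, , drop = FALSE]
  rig <- !at(r, cc + 1L)
  es[[4]] <- cbind(cc, r, cc, r - 1L)[rig, , drop = FALSE]
  E <- do.call(rbind, es)
  nE <- nrow(E)
  key <- function(col, row) row * (W + 1L) + col + 1L
  fromKey <- key(E[, 1], E[, 2])
  ord <- order(fromKey)
  # adjacency: for each vertex, the (<= 2) outgoing edges
  used <- rep(FALSE, nE)
  outIdx <- split(ord, fromKey[ord])  # names are keys
  bestRing <- NULL; bestArea <- -Inf
  for (e0 in seq_len(nE)) {
    if (used[e0]) next
    ring <- matrix(0L, nE + 1L, 2L)
    e <- e0; np <- 0L
    repeat {
      used[e] <- TRUE
      np <- np + 1L
      ring[np, ] <- E[e, 1:2]
      endKey <- key(E[e, 3], E[e, 4])
      cand <- outIdx[[as.character(endKey)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) { np <- np + 1L; ring[np, ] <- E[e, 3:4]; break }
      if (length(cand) == 1L) { e <- cand[1] } else {
        # world heading: (dcol, -drow); sharpest right = min cross product
        hx <- E[e, 3] - E[e, 1]; hy <- -(E[e, 4] - E[e, 2])
        cx <- E[cand, 3] - E[cand, 1]; cy <- -(E[cand, 4] - E[cand, 2])
        e <- cand[which.min(hx * cy - hy * cx)]
      }
    }
    pts <- ring[seq_len(np), , drop = FALSE]
    x <- pts[, 1]; y <- -pts[, 2]  # world orientation
    a <- sum(x[-np] * y[-1] - x[-1] * y[-np]) / 2
    if (a > bestArea) { bestArea <- a; bestRing <- pts }
  }
  bestRing
}

#' Crown area from a labelled region set
#'
#' Areas are `pixelCount * pixelSize^2` (m2); this accessor is equivalent
#' to `regionTable(x)$area`.
#'
#' @param regions a [CrownRegionSet-class].
#' @param pixelSize optional override; areas are rescaled to this ground
#'   sample distance.
#' @return numeric vector of areas, m2.
#' @export
crownArea <- function(regions, pixelSize = NULL) {
  stopifnot(methods::is(regions, "CrownRegionSet"))
  ps <- if (is.null(pixelSize)) regions@pixelSize else pixelSize
  regions@regions$pixelCount * ps^2
}

#' Write delineated regions as CSV or GeoJSON
#'
#' CSV columns: `label,pixel_count,area_m2,centroid_x,centroid_y`. GeoJSON:
#' a FeatureCollection of outline polygons with the same properties.
#'
#' @param regions a [CrownRegionSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsCSV <- function(regions, path) {
  r <- regionTable(regions)
  out <- data.frame(label = r$label, pixel_count = r$pixelCount,
                    area_m2 = r$area, centroid_x = r$centroidX,
                    centroid_y = r$centroidY)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRegionsCSV
#' @export
writeRegionsGeoJSON <- function(regions, path) {
  r <- regionTable(regions)
  rings <- crownOutlines(regions)
  if (length(rings) != nrow(r))
    validationError("region set has no outlines; relabel with outlines = TRUE")
  feats <- lapply(seq_len(nrow(r)), function(i) {
    ring <- rings[[i]]
    list(type = "Feature",
         properties = list(label = r$label[i], pixel_count = r$pixelCount[i],
                           area_m2 = r$area[i], centroid_x = r$centroidX[i],
                           centroid_y = r$centroidY[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) c(ring[j, 1], ring[j, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
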