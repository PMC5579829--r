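#' Build a per-tree thematic yield map
#'
#' Applies the chained crown-area forecast ([forecastAYfromICA()]) to every
#' delineated crown and bins the forecast yields into discrete classes —
#' by default quantile classes, or fixed edges if supplied. Both chained
#' slopes are positive, so class ordering by yield equals class ordering by
#' crown area. The orchard-level estimate `totalOAY` is the summed forecast
#' divided by the mapped image footprint in hectares.
#'
#' @param regions a non-empty [CrownRegionSet-class].
#' @param regime `"general"`, `"irrigated"` or `"rainfed"`.
#' @param classCount number of yield classes (>= 2, default 5).
#' @param edges optional fixed class edges (kg/tree), overriding quantile
#'   classing; must be increasing and span the forecasts.
#' @return a [YieldMap-class].
#' @export
buildYieldMap <- function(regions, regime = c("general", "irrigated", "rainfed"),
                          classCount = 5L, edges = NULL) {
  regime <- match.arg(regime)
  stopifnot(methods::is(regions, "CrownRegionSet"))
  if (length(regions) == 0L) validationError("no regions to map")
  if (is.null(edges) && classCount < 2L)
    validationError("classCount must be >= 2")
  r <- regionTable(regions)
  fc <- suppressWarnings(forecastAYfromICA(r$area, regime))
  if (is.null(edges)) {
    edges <- unique(stats::quantile(fc$ay, probs = seq(0, 1, length.out = classCount + 1),
                                    names = FALSE))
    if (length(edges) < 2L) edges <- c(edges, edges + 1e-9)
  } else {
    edges <- sort(as.numeric(edges))
    if (min(fc$ay) < edges[1] || max(fc$ay) > edges[length(edges)])
      validationError("fixed class edges do not span the forecast yields")
  }
  cls <- findInterval(fc$ay, edges, all.inside = TRUE)
  feats <- data.frame(label = r$label, centroidX = r$centroidX,
                      centroidY = r$centroidY, ica = fc$ica,
                      mcvEst = fc$mcv_est, ayForecast = fc$ay,
                      classIndex = cls)
  footprintHa <- prod(regions@maskDim) * pixelSize(regions)^2 / 10000
  methods::new("YieldMap", features = feats, outlines = crownOutlines(regions),
               classEdges = edges, regime = regime,
               totalOAY = sum(fc$ay) / footprintHa, footprintHa = footprintHa)
}

#' Export a yield map as GeoJSON, CSV or a rendered PNG
#'
#' GeoJSON: FeatureCollection of crown outline polygons with properties
#' `ica_m2`, `mcv_m3`, `ay_kg`, `class`. CSV: the feature table. PNG: the
#' classed map drawn with a discrete colour ramp and a legend.
#'
#' @param map a [YieldMap-class].
#' @param path output path.
#' @param format `"geojson"`, `"csv"` or `"png"`.
#' @return `path`, invisibly.
#' @export
exportYieldMap <- function(map, path, format = c("geojson", "csv", "png")) {
  stopifnot(methods::is(map, "YieldMap"))
  if (length(format) != 1L || !format %in% c("geojson", "csv", "png"))
    validationError("unknown export format: %s", paste(format, collapse = ","))
  f <- map@features
  if (format == "csv") {
    out <- data.frame(label = f$label, centroid_x = f$centroidX,
                      centroid_y = f$centroidY, ica_m2 = f$ica,
                      mcv_m3 = f$mcvEst, ay_kg = f$ayForecast,
                      class = f$classIndex)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "geojson") {
    if (length(map@outlines) != nrow(f))
      validationError("yield map has no outlines to export")
    feats <- lapply(seq_len(nrow(f)), function(i) {
      ring <- map@outlines[[i]]
      list(type = "Feature",
           properties = list(label = f$label[i], ica_m2 = f$ica[i],
                             mcv_m3 = f$mcvEst[i], ay_kg = f$ayForecast[i],
                             class = f$classIndex[i]),
           geometry = list(type = "Polygon",
                           coordinates = list(lapply(seq_len(nrow(ring)),
                             function(j) c(ring[j, 1], ring[j, 2])))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats,
                              properties = list(regime = map@regime,
                                                class_edges = map@classEdges,
                                                total_oay_kg_ha = map@totalOAY)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    k <- length(map@classEdges) - 1L
    cols <- grDevices::hcl.colors(k, "YlGn", rev = TRUE)
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(4, 4, 3, 1))
    haveRings <- length(map@outlines) == nrow(f)
    xr <- if (haveRings) range(unlist(lapply(map@outlines, function(m) m[, 1])))
          else range(f$centroidX)
    yr <- if (haveRings) range(unlist(lapply(map@outlines, function(m) m[, 2])))
          else range(f$centroidY)
    plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (m)", ylab = "y (m)",
         main = sprintf("Forecast on-year yield (%s), OAY %.0f kg/ha",
                        map@regime, map@totalOAY))
    for (i in seq_len(nrow(f))) {
      if (haveRings)
        graphics::polygon(map@outlines[[i]][, 1], map@outlines[[i]][, 2],
                          col = cols[f$classIndex[i]], border = NA)
      else
        graphics::points(f$centroidX[i], f$centroidY[i], pch = 16, cex = 2,
                         col = cols[f$classIndex[i]])
    }
    lab <- sprintf("%.0f-%.0f kg", map@classEdges[-(k + 1)], map@classEdges[-1])
    graphics::legend("topright", legend = lab, fill = cols, bg = "white",
                     title = "AY class")
  }
  invisible(path)
}
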