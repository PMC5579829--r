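test_that("labelling handles the small worked examples", {
  # empty mask -> empty region set
  empty <- labelRegions(matrix(FALSE, 4, 4), 1)
  expect_length(empty, 0)

  # 2x2 block plus an isolated pixel
  mk <- matrix(FALSE, 5, 5)
  mk[1:2, 1:2] <- TRUE; mk[5, 5] <- TRUE
  rs <- labelRegions(mk, 1, connectivity = 8)
  expect_length(rs, 2)
  expect_identical(regionTable(rs)$pixelCount, c(4L, 1L))
  expect_identical(regionTable(rs)$label, 1:2)   # raster-scan order

  # diagonal contact: one component under 8-connectivity, two under 4
  dg <- matrix(FALSE, 3, 3); dg[1, 1] <- TRUE; dg[2, 2] <- TRUE
  expect_length(labelRegions(dg, 1, connectivity = 8), 1)
  expect_length(labelRegions(dg, 1, connectivity = 4), 2)
})

test_that("labelling is identical to the flood-fill oracle on random masks", {
  set.seed(31)
  for (i in 1:20) {
    H <- sample(20:64, 1); W <- sample(20:64, 1)
    dens <- runif(1, 0.15, 0.7)
    mk <- matrix(runif(H * W) < dens, H, W)
    for (conn in c(4L, 8L)) {
      expect_identical(labelMask(mk, conn), floodFillOracle(mk, conn),
                       info = sprintf("mask %d, connectivity %d", i, conn))
    }
  }
})

test_that("region areas conserve the mask and scale with pixel size", {
  set.seed(32)
  mk <- matrix(runif(48 * 48) < 0.4, 48, 48)
  ps <- 0.05
  rs <- labelRegions(mk, ps, connectivity = 8, outlines = FALSE)
  r <- regionTable(rs)
  expect_identical(sum(r$pixelCount), sum(mk))   # no pixel lost or counted twice
  expect_equal(r$area, r$pixelCount * ps^2)
  expect_equal(sum(r$area), sum(mk) * ps^2)

  # areas scale by k^2 when the pixel size scales by k
  rs2 <- labelRegions(mk, ps * 3, connectivity = 8, outlines = FALSE)
  expect_equal(regionTable(rs2)$area, r$area * 9)

  # translation and 90-degree rotation leave the area multiset unchanged
  shift <- matrix(FALSE, 58, 58); shift[6:53, 6:53] <- mk
  rot <- t(mk)[, rev(seq_len(48))]
  areas <- sort(r$area)
  expect_equal(sort(regionTable(labelRegions(shift, ps, outlines = FALSE))$area), areas)
  expect_equal(sort(regionTable(labelRegions(rot, ps, outlines = FALSE))$area), areas)
})

test_that("minArea discards speckle and maxArea flags merged crowns", {
  mk <- matrix(FALSE, 10, 10)
  mk[1:4, 1:4] <- TRUE    # 16 px
  mk[8, 8] <- TRUE        # 1 px speckle
  rs <- labelRegions(mk, 1, minArea = 2)
  expect_length(rs, 1)
  expect_identical(regionTable(rs)$pixelCount, 16L)
  expect_warning(labelRegions(mk, 1, minArea = 0, maxArea = 10),
                 "merged crowns")
  expect_error(labelRegions(mk, 1, connectivity = 5), class = "validationError")
  expect_error(labelRegions(matrix(1, 2, 2), 1), class = "validationError")
})

test_that("outlines are closed counter-clockwise rings enclosing the pixels", {
  # hole-free shapes: ring area equals the pixel count exactly
  mk <- matrix(FALSE, 30, 30)
  mk[5:12, 4:20] <- TRUE                       # rectangle
  for (r in 1:30) for (cc in 1:30)             # ellipse
    if (((r - 22) / 6)^2 + ((cc - 15) / 10)^2 <= 1) mk[r, cc] <- TRUE
  rs <- labelRegions(mk, 0.5, connectivity = 8)
  r <- regionTable(rs)
  rings <- crownOutlines(rs)
  expect_length(rings, nrow(r))
  for (i in seq_len(nrow(r))) {
    ring <- rings[[i]]
    expect_identical(ring[1, ], ring[nrow(ring), ])   # closed
    a <- ringArea(ring)
    expect_gt(a, 0)                                   # counter-clockwise
    expect_equal(a, r$area[i], tolerance = 1e-12)
  }

  # world coordinates: single pixel at image row 1, col 1 with origin (0, H*ps)
  one <- matrix(FALSE, 4, 4); one[1, 1] <- TRUE
  ro <- labelRegions(one, 2)
  expect_equal(regionTable(ro)$centroidX, 1)
  expect_equal(regionTable(ro)$centroidY, 7)
  ring <- crownOutlines(ro)[[1]]
  expect_setequal(ring[-nrow(ring), 1], c(0, 2))
  expect_setequal(ring[-nrow(ring), 2], c(6, 8))
})

test_that("region tables export to CSV and GeoJSON", {
  mk <- matrix(FALSE, 8, 8); mk[2:4, 2:4] <- TRUE; mk[6:7, 6:7] <- TRUE
  rs <- labelRegions(mk, 0.5)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeRegionsCSV(rs, csv)
  back <- read.csv(csv)
  expect_identical(nrow(back), 2L)
  expect_equal(back$area_m2, regionTable(rs)$area)

  gj <- withr::local_tempfile(fileext = ".geojson")
  writeRegionsGeoJSON(rs, gj)
  feats <- jsonlite::read_json(gj)
  expect_identical(feats$type, "FeatureCollection")
  expect_length(feats$features, 2)
  expect_equal(feats$features[[1]]$properties$area_m2,
               regionTable(rs)$area[1])
  expect_identical(feats$features[[1]]$geometry$type, "Polygon")
})
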