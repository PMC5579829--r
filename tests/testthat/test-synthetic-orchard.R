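test_that("generated trees are internally consistent with the volume model", {
  spec <- orchardSpec(c(6, 3), regime = "rainfed", category = "traditional",
                      seed = 51)
  trees <- generateOrchard(spec)
  expect_equal(nrow(trees), 555)   # floor(10000 / 18) on 1 ha
  # ellipsoid model applied to stored geometry reproduces the latent volume
  mcvBack <- manualCanopyVolume(trees$d1, trees$d2, trees$canopy_height,
                                trees$canopy_height, 0, 0)
  expect_equal(mcvBack, trees$true_mcv, tolerance = 1e-9)
  expect_equal(trees$true_ica, pi * trees$d1 * trees$d2 / 4, tolerance = 1e-12)
  expect_true(all(trees$true_mcv > 1 & trees$canopy_height > 0.5 &
                  trees$true_ay >= 0))
  expect_true(all(trees$x >= 0 & trees$x <= 100 & trees$y >= 0 & trees$y <= 100))
})

test_that("generation is deterministic in the seed and noiseless in the limit", {
  spec <- orchardSpec(c(7, 5), regime = "irrigated", category = "intensive",
                      seed = 52)
  expect_identical(generateOrchard(spec), generateOrchard(spec))
  spec2 <- orchardSpec(c(7, 5), regime = "irrigated", category = "intensive",
                       seed = 53)
  expect_false(identical(generateOrchard(spec)$true_ay,
                         generateOrchard(spec2)$true_ay))

  # zero residual SD puts every yield exactly on the regime line
  spec0 <- orchardSpec(c(7, 5), regime = "irrigated", category = "intensive",
                       residualSd = 0, seed = 54)
  t0 <- generateOrchard(spec0)
  expect_equal(t0$true_ay, forecastAYfromMCV(t0$true_mcv, "irrigated"),
               tolerance = 1e-12)
})

test_that("grid and quincunx layouts respect spacing and field bounds", {
  spec <- orchardSpec(c(12, 12), fieldSize = c(50, 50), regime = "rainfed",
                      category = "traditional", layout = "quincunx", seed = 55)
  trees <- generateOrchard(spec)
  ys <- sort(unique(trees$y))
  expect_equal(diff(ys), rep(12, length(ys) - 1))
  xsEven <- sort(unique(trees$x[trees$y == ys[1]]))
  xsOdd <- sort(unique(trees$x[trees$y == ys[2]]))
  expect_equal(xsOdd[1] - xsEven[1], 6)   # alternate rows offset by a/2

  expect_error(generateOrchard(orchardSpec(c(30, 30), fieldSize = c(10, 10))),
               class = "validationError")
  expect_error(orchardSpec(c(6, 3), regime = "rainfed", category = "intensive"),
               class = "validationError")   # no reported population
})

test_that("large populations recover the generating regression", {
  spec <- orchardSpec(c(6, 3), regime = "rainfed", category = "traditional",
                      seed = 56)
  set.seed(56)
  pop <- sampleTreePopulation(4000, spec)
  m <- fitOLS(pop$true_mcv, pop$true_ay)
  ci <- confint(m)
  expect_true(ci["slope", 1] <= 0.781 && 0.781 <= ci["slope", 2])
  expect_true(ci["intercept", 1] <= 25.932 && 25.932 <= ci["intercept", 2])
  expect_equal(seEstimate(m), 17.1, tolerance = 0.05)

  # crown area predicts volume geometrically; r2 -> 1 as height spread -> 0
  specH0 <- orchardSpec(c(6, 3), regime = "rainfed", category = "traditional",
                        canopyHeightSd = 1e-6, seed = 57)
  set.seed(57)
  popH0 <- sampleTreePopulation(1000, specH0)
  mg <- fitOLS(popH0$true_ica, popH0$true_mcv)
  expect_gt(coef(mg)["slope"], 0)
  expect_gt(rSquared(mg), 0.9999)
  expect_equal(unname(coef(mg)["slope"]), 3.9 / 1.5, tolerance = 1e-3)
})

test_that("rendered crowns rasterize to the analytic ellipse area", {
  spec <- orchardSpec(c(10, 10), fieldSize = c(10, 10), regime = "irrigated",
                      category = "traditional", pixelSize = 0.02,
                      sunVector = c(0, 0), seed = 58)
  trees <- data.frame(tree_id = 1L, x = 5, y = 5, true_mcv = 8 * pi * 4 / 6,
                      true_ica = pi * 4, true_ay = 50, d1 = 4, d2 = 4,
                      canopy_height = 2)
  set.seed(58)
  img <- renderOrthoimage(trees, spec)
  ch <- extractChannel(img, "green")
  crownCount <- sum(ch < 140)   # crown mode 96 vs soil 172, noise sd 6
  analytic <- pi * 2^2 / 0.02^2   # 31416 px
  perimBand <- pi * 4 / 0.02      # one pixel band around the circumference
  expect_lt(abs(crownCount - analytic), perimBand)
  # sun vector (0, 0): shadow fully occluded, no dark pixels anywhere
  expect_gt(min(ch), 60)

  # zero trees: pure soil, no regions after segmentation
  set.seed(59)
  img0 <- renderOrthoimage(trees[0, ], spec)
  thr <- suggestThresholds(extractChannel(img0, "green"))
  msk <- extractChannel(img0, "green") > thr$shadow &
    extractChannel(img0, "green") <= thr$ground
  rs <- labelRegions(msk, 0.02, minArea = 1)
  expect_length(rs, 0)
})

test_that("rendered-then-segmented areas match the generated crowns", {
  o <- smallOrchard(seed = 60, pixelSize = 0.05)
  set.seed(60)
  img <- renderOrthoimage(o$trees, o$spec)
  thr <- suggestThresholds(extractChannel(img, "green"))
  mask <- segmentCanopy(img, segmentationParams(thr$ground, thr$shadow))
  rs <- labelRegions(mask, pixelSize(img), minArea = 1,
                     origin = imageOrigin(img), outlines = FALSE)
  expect_length(rs, nrow(o$trees))
  r <- regionTable(rs)
  nearest <- vapply(seq_len(nrow(o$trees)), function(i)
    which.min((r$centroidX - o$trees$x[i])^2 + (r$centroidY - o$trees$y[i])^2),
    integer(1))
  expect_identical(sort(nearest), seq_len(nrow(o$trees)))
  relErr <- abs(r$area[nearest] - o$trees$true_ica) / o$trees$true_ica
  expect_lt(max(relErr), 0.05)
})

test_that("ground-truth tables round-trip through CSV", {
  o <- smallOrchard(seed = 61)
  path <- withr::local_tempfile(fileext = ".csv")
  writeGroundTruth(o$trees, path)
  back <- readGroundTruth(path)
  expect_equal(nrow(back), nrow(o$trees))
  expect_equal(back$true_mcv, o$trees$true_mcv, tolerance = 1e-6)
  expect_equal(back$d2, o$trees$d2, tolerance = 1e-6)
  expect_error(writeGroundTruth(o$trees[0, ], path), class = "validationError")
  expect_error(readGroundTruth("no/such.csv"), class = "ioError")
})
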