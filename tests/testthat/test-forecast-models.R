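test_that("closed-form OLS matches stats::lm to 1e-9 relative", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    x <- rnorm(n, 50, 20)
    y <- 3 + 0.8 * x + rnorm(n, 0, 5)
    m <- fitOLS(x, y)
    ref <- lm(y ~ x)
    expect_equal(unname(coef(m)), unname(coef(ref)), tolerance = 1e-9)
    expect_equal(rSquared(m), summary(ref)$r.squared, tolerance = 1e-9)
    expect_equal(seEstimate(m), summary(ref)$sigma, tolerance = 1e-9)
    expect_equal(unname(c(m@interceptSE, m@slopeSE)),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-9)
    expect_equal(unname(confint(m)), unname(confint(ref)), tolerance = 1e-9)
  }
})

test_that("OLS handles exact, degenerate and permuted inputs", {
  m <- fitOLS(c(0, 1, 2), c(1, 2, 3))
  expect_equal(unname(coef(m)), c(1, 1))
  expect_equal(rSquared(m), 1)
  expect_equal(seEstimate(m), 0)

  m2 <- fitOLS(c(0, 1, 2), c(0, 1, 0))
  expect_equal(unname(coef(m2)), c(1 / 3, 0), tolerance = 1e-12)

  set.seed(42)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  p <- sample(20)
  expect_equal(coef(fitOLS(x[p], y[p])), coef(fitOLS(x, y)), tolerance = 1e-12)

  expect_error(fitOLS(c(1, 1, 1), c(1, 2, 3)), class = "validationError")
  expect_error(fitOLS(c(1, 2), c(1, 2)), class = "validationError")
  expect_error(fitOLS(1:4, 1:3), class = "validationError")
})

test_that("published forecast equations reproduce their printed coefficients", {
  pm <- publishedModels()
  expect_equal(predict(pm$general, 0), 15.928)
  expect_equal(predict(pm$general, 10), 28.078)
  expect_equal(predict(pm$irrigated, 0), 10.642)
  expect_equal(predict(pm$irrigated, 96.4), 10.642 + 1.541 * 96.4)
  expect_equal(predict(pm$rainfed, 0), 25.932)
  expect_equal(predict(pm$rainfed, 1), 25.932 + 0.781)
  expect_equal(predict(pm$mcv_from_ica, 0), -7.906)
  expect_equal(predict(pm$mcv_from_ica, 1), -7.906 + 3.080)
  expect_equal(forecastAYfromMCV(0, "general"), 15.928)
  expect_equal(forecastAYfromMCV(0, "rainfed"), 25.932)
  expect_error(forecastAYfromMCV(10, "dryland"))
})

test_that("prediction is exactly linear and never clamped", {
  pm <- publishedModels()
  set.seed(43)
  x1 <- runif(20, -50, 200); x2 <- runif(20, -50, 200)
  for (m in pm) {
    expect_equal(predict(m, x1) + predict(m, x2) - predict(m, 0),
                 predict(m, x1 + x2), tolerance = 1e-12)
  }
  # small crowns: negative volume estimate kept, not clamped
  expect_lt(suppressWarnings(forecastAYfromICA(0, "general"))$mcv_est, 0)
})

test_that("the chained crown-area forecast equals manual composition", {
  pm <- publishedModels()
  fc <- forecastAYfromICA(34.8, "irrigated")
  expect_equal(fc$mcv_est, -7.906 + 3.080 * 34.8)   # 99.278
  expect_equal(fc$ay, 10.642 + 1.541 * (-7.906 + 3.080 * 34.8))
  expect_equal(fc$ay, 163.629, tolerance = 1e-3)

  # root of the area-volume line maps to the yield intercept
  icaRoot <- 7.906 / 3.080
  fc0 <- forecastAYfromICA(icaRoot, "general")
  expect_equal(fc0$mcv_est, 0, tolerance = 1e-12)
  expect_equal(fc0$ay, 15.928)

  # chained result identical to composing the two models by hand
  set.seed(44)
  ica <- runif(50, 3, 60)
  fcv <- suppressWarnings(forecastAYfromICA(ica, "rainfed"))
  manual <- predict(pm$rainfed,
                    predict(pm$mcv_from_ica, ica, warnOutOfRange = FALSE),
                    warnOutOfRange = FALSE)
  expect_identical(fcv$ay, manual)

  expect_warning(forecastAYfromICA(0.5, "general"), "negative volume")
})

test_that("forecast-vs-measured agreement reuses the OLS fit", {
  x <- c(10, 20, 30, 40)
  id <- compareForecastToMeasured(x, x)
  expect_equal(id$slope, 1); expect_equal(id$r2, 1)
  dbl <- compareForecastToMeasured(x, 2 * x)
  expect_equal(dbl$slope, 2)

  # with the generator's own noise the slope stays near 1:1
  set.seed(45)
  mcv <- pmax(rnorm(300, 98, 9.9), 1)
  ay <- forecastAYfromMCV(mcv, "irrigated") + rnorm(300, 0, 13.1)
  cmp <- compareForecastToMeasured(forecastAYfromMCV(mcv, "irrigated"), ay)
  ci <- confint(cmp$model)["slope", ]
  expect_true(ci[1] <= 1 && 1 <= ci[2])
})

test_that("models serialize to JSON and back", {
  m <- fitOLS(c(1, 3, 5, 9), c(2, 5, 11, 19), "MCV", "AY")
  path <- withr::local_tempfile(fileext = ".json")
  writeLinearModel(m, path)
  back <- readLinearModel(path)
  expect_equal(coef(back), coef(m))
  expect_equal(rSquared(back), rSquared(m))
  expect_equal(back@validRange, m@validRange)
  expect_identical(back@source, "fitted")

  pub <- publishedModels()$irrigated
  writeLinearModel(pub, path)
  back2 <- readLinearModel(path)
  expect_equal(coef(back2), coef(pub))
  expect_true(is.na(back2@slopeSE))
  expect_error(confint(back2), class = "validationError")
})
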