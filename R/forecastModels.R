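#' Fit a simple linear model by closed-form least squares
#'
#' Ordinary least squares for a single predictor, computed with two-pass
#' mean-centred sums for numerical stability:
#' `slope = Sxy / Sxx`, `intercept = mean(y) - slope * mean(x)`,
#' `r2 = 1 - SSE/SST`, and the standard error of the estimate
#' `sqrt(SSE / (n - 2))`. Coefficient standard errors use the usual
#' t-theory formulas (`df = n - 2`).
#'
#' @param x predictor values (not all equal), length >= 3.
#' @param y response values, same length.
#' @param predictorLabel,responseLabel axis labels stored on the model.
#' @return a [LinearModel-class] with `source = "fitted"`.
#' @export
fitOLS <- function(x, y, predictorLabel = "x", responseLabel = "y") {
  assertNumeric(x, "x"); assertNumeric(y, "y")
  n <- length(x)
  if (n != length(y)) validationError("x and y must have equal length")
  if (n < 3L) validationError("need at least 3 observations")
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx^2)
  if (sxx == 0) validationError("x is constant: slope undefined")
  slope <- sum(dx * dy) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  sse <- sum(resid^2)
  sst <- sum(dy^2)
  r2 <- if (sst == 0) 1 else max(0, min(1, 1 - sse / sst))
  se <- sqrt(sse / (n - 2))
  methods::new("LinearModel", intercept = intercept, slope = slope, r2 = r2,
               seEstimate = se, slopeSE = se / sqrt(sxx),
               interceptSE = se * sqrt(1 / n + mx^2 / sxx),
               n = as.integer(n), predictorLabel = predictorLabel,
               responseLabel = responseLabel, validRange = range(x),
               source = "fitted")
}

#' Predict from a LinearModel
#'
#' Returns `intercept + slope * x`, unclamped. Predictor values outside the
#' model's fit-time range are allowed but flagged with a warning (linear
#' extrapolation is the caller's responsibility).
#'
#' @param object a [LinearModel-class].
#' @param newdata numeric predictor values.
#' @param warnOutOfRange warn on extrapolation beyond `validRange`.
#' @return numeric predictions in response units.
#' @export
setMethod("predict", "LinearModel",
  function(object, newdata, warnOutOfRange = TRUE) {
    assertNumeric(newdata, "newdata")
    vr <- object@validRange
    if (warnOutOfRange && !anyNA(vr) &&
        any(newdata < vr[1] | newdata > vr[2]))
      warning(sprintf("%d value(s) outside the model's %s range [%.3g, %.3g]",
                      sum(newdata < vr[1] | newdata > vr[2]),
                      object@predictorLabel, vr[1], vr[2]))
    object@intercept + object@slope * newdata
  })

#' @describeIn fitOLS t-based confidence intervals for the coefficients of
#'   a fitted model (rows `intercept`, `slope`).
#' @param object a fitted [LinearModel-class].
#' @param level confidence level.
#' @param parm,... ignored (both coefficients are always returned).
#' @export
setMethod("confint", "LinearModel",
  function(object, parm, level = 0.95, ...) {
    if (object@source != "fitted" || is.na(object@slopeSE))
      validationError("confidence intervals need a fitted model")
    tq <- stats::qt(1 - (1 - level) / 2, df = object@n - 2L)
    est <- c(object@intercept, object@slope)
    se <- c(object@interceptSE, object@slopeSE)
    out <- cbind(lower = est - tq * se, upper = est + tq * se)
    rownames(out) <- c("intercept", "slope")
    out
  })

#' The published olive yield forecast models
#'
#' The four reported forecast equations for southern-Spain olive orchards,
#' as immutable [LinearModel-class] objects:
#' \itemize{
#'   \item `general`: AY = 15.928 + 1.215 MCV (r2 0.76, SE 18.6 kg/tree,
#'     n = 518 trees over four on-years)
#'   \item `irrigated`: AY = 10.642 + 1.541 MCV (r2 0.89, SE 13.1 kg/tree)
#'   \item `rainfed`: AY = 25.932 + 0.781 MCV (r2 0.62, SE 17.1 kg/tree)
#'   \item `mcv_from_ica`: MCV = -7.906 + 3.080 ICA (r2 0.83,
#'     SE 16.77 m3/tree, n = 36 trees)
#' }
#' AY is per-tree actual on-year yield (kg/tree), MCV the manual canopy
#' volume (m3) and ICA the individual crown area (m2). The r2 and standard
#' errors are the reported values, carried as metadata: they cannot be
#' recomputed without the original field data.
#'
#' @return named list of `LinearModel` objects.
#' @export
publishedModels <- function() {
  mk <- function(a, b, r2, se, n, px, py)
    methods::new("LinearModel", intercept = a, slope = b, r2 = r2,
                 seEstimate = se, n = n, predictorLabel = px,
                 responseLabel = py, source = "published")
  list(
    general      = mk(15.928, 1.215, 0.76, 18.6, 518L, "MCV", "AY"),
    irrigated    = mk(10.642, 1.541, 0.89, 13.1, NA_integer_, "MCV", "AY"),
    rainfed      = mk(25.932, 0.781, 0.62, 17.1, NA_integer_, "MCV", "AY"),
    mcv_from_ica = mk(-7.906, 3.080, 0.83, 16.77, 36L, "ICA", "MCV"))
}

#' Forecast per-tree yield from manual canopy volume
#'
#' Applies the published regime model (general, irrigated or rainfed) to a
#' canopy volume in m3 and returns the actual on-year yield forecast in
#' kg/tree. Predictions are never clamped.
#'
#' @param mcv manual canopy volume, m3 (vectorised).
#' @param regime `"general"`, `"irrigated"` or `"rainfed"`.
#' @return forecast AY, kg/tree.
#' @export
forecastAYfromMCV <- function(mcv, regime = c("general", "irrigated", "rainfed")) {
  regime <- match.arg(regime)
  assertNumeric(mcv, "mcv")
  if (any(mcv < 0))
    warning("negative canopy volume supplied; forecast extrapolates the linear model")
  predict(publishedModels()[[regime]], mcv, warnOutOfRange = FALSE)
}

#' Chained yield forecast from individual crown area
#'
#' The two-step forecast that replaces the manual canopy volume with the
#' image-derived crown area: first `MCV = -7.906 + 3.080 ICA`, then the
#' regime yield model applied to the estimated volume. Small crowns
#' (ICA < 7.906/3.080 = 2.567 m2) give a negative volume estimate; the
#' value is kept (predictions are unclamped) but flagged with a warning.
#'
#' @param ica individual crown area, m2 (vectorised).
#' @param regime `"general"`, `"irrigated"` or `"rainfed"`.
#' @return data.frame with columns `ica`, `mcv_est` (m3) and `ay` (kg/tree).
#' @export
forecastAYfromICA <- function(ica, regime = c("general", "irrigated", "rainfed")) {
  regime <- match.arg(regime)
  assertNumeric(ica, "ica", nonneg = TRUE)
  mcvEst <- predict(publishedModels()$mcv_from_ica, ica, warnOutOfRange = FALSE)
  if (any(mcvEst < 0))
    warning(sprintf("%d crown(s) below the area-volume model's domain: negative volume estimate",
                    sum(mcvEst < 0)))
  ay <- suppressWarnings(forecastAYfromMCV(mcvEst, regime))
  data.frame(ica = ica, mcv_est = mcvEst, ay = ay)
}

#' Agreement between forecast and measured yields
#'
#' Fits measured-on-predicted by [fitOLS()]; a slope near 1 with high r2
#' indicates the forecast tracks the 1:1 line.
#'
#' @param predicted forecast yields, kg/tree.
#' @param measured observed yields, kg/tree.
#' @return list with `slope`, `r2` and the full `model`.
#' @export
compareForecastToMeasured <- function(predicted, measured) {
  m <- fitOLS(predicted, measured, "predicted AY", "measured AY")
  list(slope = unname(coef(m)["slope"]), r2 = rSquared(m), model = m)
}

#' Serialize a LinearModel to JSON (and back)
#'
#' @param model a [LinearModel-class].
#' @param path JSON path.
#' @return `writeLinearModel`: `path` invisibly; `readLinearModel`: the model.
#' @export
writeLinearModel <- function(model, path) {
  stopifnot(methods::is(model, "LinearModel"))
  jsonlite::write_json(list(
    intercept = model@intercept, slope = model@slope, r2 = model@r2,
    se_estimate = model@seEstimate, slope_se = model@slopeSE,
    intercept_se = model@interceptSE, n = model@n,
    predictor = model@predictorLabel, response = model@responseLabel,
    valid_range = model@validRange, source = model@source),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeLinearModel
#' @export
readLinearModel <- function(path) {
  if (!file.exists(path)) ioError("model file not found: %s", path)
  j <- jsonlite::read_json(path)
  num <- function(z) if (is.null(z)) NA_real_ else as.numeric(z)
  methods::new("LinearModel", intercept = num(j$intercept),
               slope = num(j$slope), r2 = num(j$r2),
               seEstimate = num(j$se_estimate), slopeSE = num(j$slope_se),
               interceptSE = num(j$intercept_se),
               n = if (is.null(j$n)) NA_integer_ else as.integer(j$n),
               predictorLabel = j$predictor, responseLabel = j$response,
               validRange = vapply(j$valid_range, num, numeric(1)),
               source = j$source)
}
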