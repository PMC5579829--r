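#' Manual canopy volume from surveying-rod measurements
#'
#' Computes the ellipsoid approximation of a tree's canopy volume from two
#' perpendicular crown diameters and the mean canopy height (tree height
#' minus skirt height, averaged over the two measurement positions):
#' \deqn{MCV = \frac{\pi}{6}\, D_1 D_2 \,\frac{(Ht_1-Hs_1)+(Ht_2-Hs_2)}{2}}
#' This is the volume of an ellipsoid with horizontal axes `d1`, `d2` and
#' vertical axis equal to the mean canopy height.
#'
#' @param d1,d2 crown diameters in the two perpendicular passes, m.
#' @param ht1,ht2 tree heights, m.
#' @param hs1,hs2 skirt heights (lowest canopy height above ground), m.
#'   Must satisfy `0 <= hs <= ht` pass-wise.
#' @return canopy volume, m3 (vectorised over trees).
#' @examples
#' manualCanopyVolume(6, 6, 4, 4, 1, 1)  # 18 * pi
#' @export
manualCanopyVolume <- function(d1, d2, ht1, ht2, hs1 = 0, hs2 = 0) {
  args <- list(d1 = d1, d2 = d2, ht1 = ht1, ht2 = ht2, hs1 = hs1, hs2 = hs2)
  for (nm in names(args)) assertNumeric(args[[nm]], nm, nonneg = TRUE)
  if (any(hs1 > ht1) || any(hs2 > ht2))
    validationError("skirt height exceeds tree height")
  (pi / 6) * d1 * d2 * ((ht1 - hs1) + (ht2 - hs2)) / 2
}

#' Planting density from tree spacing
#'
#' Trees per hectare implied by a rectangular planting pattern, using the
#' floor convention: `floor(10000 / (a * b))`. Flooring reproduces the
#' densities printed for the common southern-Spain layouts (6 x 3 m -> 555,
#' 8 x 9 m -> 138, ...); the one exception, 12 x 12 m, is conventionally
#' quoted as 70 trees/ha although 10000/144 floors to 69.
#'
#' @param spacingA,spacingB tree spacing along and between rows, m.
#' @return trees per hectare (integer-valued).
#' @export
plantingDensity <- function(spacingA, spacingB) {
  assertNumeric(spacingA, "spacingA", positive = TRUE)
  assertNumeric(spacingB, "spacingB", positive = TRUE)
  floor(10000 / (spacingA * spacingB))
}

#' Orchard-level aggregates from per-tree yield and canopy volume
#'
#' Scales per-tree quantities to the hectare: orchard actual yield
#' `OAY = mean(AY) x density` (kg/ha), orchard canopy volume
#' `mean(MCV) x density` (m3/ha), and production per canopy volume as the
#' mean (with SD) of the per-tree `AY / MCV` ratios (kg/m3). Trees with
#' zero canopy volume are excluded from the ratio with a warning.
#'
#' @param ay per-tree actual yield, kg/tree.
#' @param mcv per-tree manual canopy volume, m3.
#' @param density planting density, trees/ha.
#' @return list with elements `oay`, `orchardCanopyVolume`,
#'   `productionPerVolume`, `productionPerVolumeSd`, `plantingDensity`, `n`.
#' @export
orchardAggregates <- function(ay, mcv, density) {
  if (length(ay) == 0L || length(ay) != length(mcv))
    validationError("ay and mcv must be non-empty and of equal length")
  assertNumeric(ay, "ay", nonneg = TRUE)
  assertNumeric(mcv, "mcv", nonneg = TRUE)
  assertNumeric(density, "density", positive = TRUE)
  ok <- mcv > 0
  if (!all(ok))
    warning(sprintf("%d tree(s) with zero canopy volume excluded from kg/m3 ratio",
                    sum(!ok)))
  ratios <- ay[ok] / mcv[ok]
  list(oay = mean(ay) * density,
       orchardCanopyVolume = mean(mcv) * density,
       productionPerVolume = if (length(ratios)) mean(ratios) else NA_real_,
       productionPerVolumeSd = if (length(ratios) > 1) stats::sd(ratios) else NA_real_,
       plantingDensity = density,
       n = length(ay))
}

#' Read or write a per-tree canopy measurement table
#'
#' CSV interface for rod measurement tables with the columns
#' `tree_id,d1,d2,ht1,ht2,hs1,hs2` (header required, decimal point, metres).
#' Reading validates the measurement invariants.
#'
#' @param path file path.
#' @param measurements data.frame with the columns above.
#' @return `readCanopyMeasurements`: validated data.frame.
#' @export
readCanopyMeasurements <- function(path) {
  if (!file.exists(path)) ioError("measurement table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "d1", "d2", "ht1", "ht2", "hs1", "hs2")
  if (!all(need %in% names(df)))
    validationError("measurement table must have columns: %s",
                    paste(need, collapse = ","))
  # validates invariants as a side effect
  manualCanopyVolume(df$d1, df$d2, df$ht1, df$ht2, df$hs1, df$hs2)
  df[need]
}

#' @rdname readCanopyMeasurements
#' @export
writeCanopyMeasurements <- function(measurements, path) {
  need <- c("tree_id", "d1", "d2", "ht1", "ht2", "hs1", "hs2")
  if (!all(need %in% names(measurements)))
    validationError("measurement table must have columns: %s",
                    paste(need, collapse = ","))
  utils::write.csv(measurements[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
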