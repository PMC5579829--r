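# Brute-force flood-fill labelling: the independent oracle for the
# run/union-find implementation. Raster scan, explicit stack, labels in
# first-pixel order.
floodFillOracle <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  stackR <- integer(H * W); stackC <- integer(H * W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    cur <- cur + 1L
    top <- 1L; stackR[1] <- r; stackC[1] <- cc; lab[r, cc] <- cur
    while (top > 0L) {
      pr <- stackR[top]; pc <- stackC[top]; top <- top - 1L
      for (k in seq_along(dr)) {
        nr <- pr + dr[k]; nc <- pc + dc[k]
        if (nr >= 1L && nr <= H && nc >= 1L && nc <= W &&
            mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- cur
          top <- top + 1L; stackR[top] <- nr; stackC[top] <- nc
        }
      }
    }
  }
  lab
}

# shoelace signed area of a closed ring
ringArea <- function(ring) {
  n <- nrow(ring)
  sum(ring[-n, 1] * ring[-1, 2] - ring[-1, 1] * ring[-n, 2]) / 2
}

# a tiny three-mode test image: soil background, one rectangular crown
# patch, one shadow patch, exact channel values (no noise)
threeModeImage <- function(H = 40, W = 40, soil = 200, crown = 100, shadow = 20,
                           pixelSize = 0.1) {
  px <- array(0L, c(H, W, 3))
  px[, , 1] <- soil; px[, , 2] <- soil; px[, , 3] <- soil
  crownRows <- 10:25; crownCols <- 8:20
  shadowRows <- 26:32; shadowCols <- 14:26
  for (ch in 1:3) {
    p <- px[, , ch]
    p[shadowRows, shadowCols] <- shadow
    p[crownRows, crownCols] <- crown
    px[, , ch] <- p
  }
  Orthoimage(px, pixelSize)
}

# a small rendered orchard reused by several test files (kept coarse so
# tests stay fast)
smallOrchard <- function(seed = 7, pixelSize = 0.05) {
  spec <- orchardSpec(c(12, 12), fieldSize = c(50, 50), regime = "irrigated",
                      category = "traditional", pixelSize = pixelSize,
                      seed = seed)
  trees <- generateOrchard(spec)
  list(spec = spec, trees = trees)
}
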