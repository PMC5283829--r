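# Shared fixtures, built in code.

# Four columns at the corners of a square: two triangles, simple geometry.
squareTessellation <- function(side = 120, r = 15, pad = 30,
                               umPerPx = 1) {
  cols <- data.frame(cx = c(pad, pad + side, pad, pad + side),
                     cy = c(pad, pad, pad + side, pad + side),
                     r = r)
  dim <- c(2 * pad + side, 2 * pad + side)
  tessellate(cols, dim, umPerPx)
}

# A small but full synthetic experiment; umPerPx = 5 keeps images modest.
smallExperiment <- function(seed, noise = TRUE, ...) {
  simulateChamberExperiment(seed = seed, umPerPx = 5, noise = noise, ...)
}

# Independent brute-force per-region mean: per-pixel loop over the raster.
bruteForceRegionMeans <- function(image, tess) {
  m <- nRegions(tess)
  sums <- numeric(m)
  cnts <- numeric(m)
  map <- tess@regionMap
  colMask <- tess@columnMask
  for (i in seq_len(nrow(image))) {
    for (j in seq_len(ncol(image))) {
      id <- map[i, j]
      if (id > 0L && !colMask[i, j]) {
        sums[id] <- sums[id] + image[i, j]
        cnts[id] <- cnts[id] + 1
      }
    }
  }
  out <- rep(NA_real_, m)
  out[cnts > 0] <- sums[cnts > 0] / cnts[cnts > 0]
  out
}
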