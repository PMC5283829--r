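test_that("columns are recovered from synthetic scenes within tolerance", {
  sim <- smallExperiment(seed = 3)
  det <- detectColumns(sim$gfp, c(40, 240) / 5)
  truth <- columnsFromLayout(sim$layout, 5)
  expect_identical(nrow(det), nrow(truth))
  # match by nearest center
  for (k in seq_len(nrow(truth))) {
    d <- sqrt((det$cx - truth$cx[k])^2 + (det$cy - truth$cy[k])^2)
    j <- which.min(d)
    expect_lt(d[j], 2)
    expect_lt(abs(det$r[j] - truth$r[k]) / truth$r[k], 0.05)
  }
  expect_error(detectColumns(matrix(100, 50, 50), c(3, 10)), "layout")
})

test_that("tessellation geometry matches brute-force and planar identities", {
  # three columns give exactly one triangle
  cols3 <- data.frame(cx = c(20, 80, 50), cy = c(20, 20, 80), r = 5)
  t3 <- tessellate(cols3, c(100, 100), 1)
  expect_identical(nRegions(t3), 1L)

  # square corners: two triangles; effective area equals an independent
  # per-pixel count and the geometric value (square minus 4 quarter disks)
  tq <- squareTessellation(side = 120, r = 15, pad = 30)
  expect_identical(nRegions(tq), 2L)
  counted <- 0
  for (i in seq_len(180)) for (j in seq_len(180)) {
    x <- j - 0.5; y <- i - 0.5
    inSquare <- x >= 30 && x <= 150 && y >= 30 && y <= 150
    inCol <- any((x - c(30, 150, 30, 150))^2 +
                   (y - c(30, 30, 150, 150))^2 <= 15^2)
    if (inSquare && !inCol) counted <- counted + 1
  }
  effTotal <- sum(effectiveArea(tq, "px"))
  expect_lt(abs(effTotal - counted) / counted, 0.005)
  geometric <- 120^2 - pi * 15^2
  expect_lt(abs(effTotal - geometric) / geometric, 0.005)

  # Euler relation and the empty-circumcircle property on random layouts
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:15, 1)
    cols <- data.frame(cx = runif(n, 20, 280), cy = runif(n, 20, 280),
                       r = 4)
    tess <- tessellate(cols, c(300, 300), 1)
    hull <- length(chull(tess@nodes))
    expect_identical(nRegions(tess), 2L * n - 2L - as.integer(hull))
    tri <- tess@triangles
    for (t_ in seq_len(nrow(tri))) {
      p <- tess@nodes[tri[t_, ], ]
      # circumcenter by perpendicular bisector intersection
      ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
      cx <- p[3, 1]; cy <- p[3, 2]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      rc <- sqrt((ax - ux)^2 + (ay - uy)^2)
      others <- setdiff(seq_len(n), tri[t_, ])
      dd <- sqrt((tess@nodes[others, 1] - ux)^2 +
                   (tess@nodes[others, 2] - uy)^2)
      expect_true(all(dd >= rc - 1e-6))
    }
  }

  collinear <- data.frame(cx = c(10, 50, 90), cy = c(10, 50, 90), r = 3)
  expect_error(tessellate(collinear, c(100, 100), 1), "collinear")
  expect_error(tessellate(collinear[1:2, ], c(100, 100), 1), "3 columns")
})

test_that("tessellation conserves area within rasterization tolerance", {
  sim <- smallExperiment(seed = 8, noise = FALSE)
  tess <- sim$tessellation
  rastered <- sum(tess@effectiveAreaPx) + sum(tess@columnAreaPx)
  hullIdx <- chull(tess@nodes)
  hullArea <- polygonArea(tess@nodes[hullIdx, 1], tess@nodes[hullIdx, 2])
  expect_lt(abs(rastered - hullArea) / hullArea, 0.005)
})

test_that("region means equal a per-pixel oracle", {
  tq <- squareTessellation(side = 60, r = 8, pad = 15)
  expect_equal(regionMeanIntensity(matrix(7.5, 90, 90), tq), c(7.5, 7.5))

  set.seed(11)
  img <- matrix(runif(90 * 90, 0, 1000), 90, 90)
  means <- regionMeanIntensity(img, tq)
  oracle <- bruteForceRegionMeans(img, tq)
  expect_lt(max(abs(means - oracle) / oracle), 1e-9)

  expect_error(regionMeanIntensity(matrix(0, 10, 10), tq), "dimensions")
})

test_that("occupancy thresholds match an exhaustive sweep oracle", {
  means <- c(10, 10, 10, 100, 100)
  # oracle: sweep every midpoint, maximize between-class variance
  cand <- (sort(unique(means))[-1] + rev(rev(sort(unique(means)))[-1])) / 2
  bcv <- sapply(cand, function(th) {
    lo <- means[means <= th]; hi <- means[means > th]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  })
  best <- cand[which.max(bcv)]
  expect_equal(otsuThreshold(means), best)
  expect_identical(callOccupancy(means, "otsu"),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))

  expect_warning(out <- callOccupancy(rep(5, 6)), "identical")
  expect_false(any(out))

  # affine intensity invariance (positive scale)
  set.seed(2)
  m2 <- c(rnorm(12, 100, 1), rnorm(5, 140, 2))
  expect_identical(callOccupancy(m2, "otsu"),
                   callOccupancy(3.7 * m2 + 55, "otsu"))
  expect_identical(callOccupancy(m2, "k_sigma"),
                   callOccupancy(3.7 * m2 + 55, "k_sigma"))

  expect_error(callOccupancy(c(1, 2, 3)), "at least 4")
})

test_that("bead-frame integration is a pixelwise union", {
  f1 <- matrix(0, 20, 20); f1[5, ] <- 9
  f2 <- matrix(0, 20, 20); f2[, 7] <- 4
  expect_identical(integrateBeadFrames(list(f1)), f1)
  integ <- integrateBeadFrames(list(f1, f2))
  # set-union oracle on thresholded pixels
  expect_identical(integ > 0, (f1 > 0) | (f2 > 0))
  expect_identical(sum(integ > 0), sum(f1 > 0) + sum(f2 > 0) - 1L)
  stack <- array(c(f1, f2), c(20, 20, 2))
  expect_identical(integrateBeadFrames(stack), integ)
  expect_error(integrateBeadFrames(list()), "empty")
})

test_that("flow scoring thresholds coverage with an inclusive boundary", {
  tq <- squareTessellation(side = 60, r = 8, pad = 15)
  expect_warning(fl <- scoreFlow(matrix(1, 90, 90), tq), "blocked")
  expect_true(all(fl == "blocked"))

  # paint exactly enough streak pixels in region 1 to sit on the boundary
  area1 <- effectiveArea(tq, "px")[1]
  nPaint <- 8L
  img <- matrix(1, 90, 90)
  idx <- which(tq@regionMap == 1L & !tq@columnMask)[seq_len(nPaint)]
  img[idx] <- 100
  fl <- scoreFlow(img, tq, minCoverage = nPaint / area1)
  expect_identical(as.character(fl[1]), "open")    # >= comparison
  fl2 <- scoreFlow(img, tq, minCoverage = nPaint / area1 + 1e-9)
  expect_identical(as.character(fl2[1]), "blocked")

  # monotone: adding streak pixels never turns open into blocked
  more <- which(tq@regionMap == 2L & !tq@columnMask)[1:20]
  img2 <- img
  img2[more] <- 100
  fl3 <- scoreFlow(img2, tq, minCoverage = nPaint / area1)
  expect_identical(as.character(fl3[1]), "open")
})
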