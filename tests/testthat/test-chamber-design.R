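test_that("FCC bed has touching unit spheres and the expected site count", {
  bed <- packSpheres(2)
  ctr <- sphereCenters(bed)
  d <- as.matrix(dist(ctr))
  diag(d) <- Inf
  expect_equal(unname(apply(d, 1, min)), rep(2, nrow(ctr)), tolerance = 1e-12)
  expect_true(all(sphereRadii(bed) == 1))

  # independent oracle: enumerate conventional FCC cells with their four
  # basis sites and count unique lattice points in the 3-cell box
  n <- 3
  a <- 2 * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  pts <- NULL
  for (i in 0:n) for (j in 0:n) for (k in 0:n)
    pts <- rbind(pts, t(a * (c(i, j, k) + t(basis))))
  pts <- pts[pts[, 1] <= n * a + 1e-9 & pts[, 2] <= n * a + 1e-9 &
               pts[, 3] <= n * a + 1e-9, ]
  nUnique <- nrow(unique(round(pts, 9)))
  expect_identical(nrow(sphereCenters(packSpheres(n))), nUnique)

  expect_error(packSpheres(1), "nPerAxis")
})

test_that("radius perturbation is uniform on [rMin, rMax] with centers fixed", {
  bed <- packSpheres(14)   # > 1e4 spheres
  expect_gt(nrow(sphereCenters(bed)), 1e4)

  same <- perturbRadii(bed, 1, 1, seed = 1)
  expect_true(all(sphereRadii(same) == 1))

  pert <- perturbRadii(bed, seed = 42)
  r <- sphereRadii(pert)
  expect_identical(sphereCenters(pert), sphereCenters(bed))
  expect_gte(min(r), 0.4)
  expect_lte(max(r), 1.0)
  se <- sqrt(0.6^2 / 12) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.7), 3 * se)

  expect_error(perturbRadii(bed, rMin = 0.9, rMax = 0.5), "rMin")
})

test_that("cross-sections obey circle geometry and reject symmetry planes", {
  one <- new("PackedBed", centers = matrix(0, 1, 3), radii = 1,
             arrangement = "fcc")
  normal <- c(1, 0.37, 0.22)

  great <- crossSection(one, normal, planeOffset = 0)
  expect_equal(great$r, 1, tolerance = 1e-12)

  off <- crossSection(one, normal, planeOffset = 0.6)
  expect_equal(off$r, 0.8, tolerance = 1e-12)

  expect_error(crossSection(one, c(1, 0, 0)), "symmetry")
  expect_error(crossSection(one, c(1, 1, 0) + 1e-4), "symmetry")
  expect_error(crossSection(one, c(0, 0, 0)), "nonzero")

  # circle radii never exceed their source sphere radii
  for (seed in 1:5) {
    bed <- perturbRadii(packSpheres(4), seed = seed)
    circ <- crossSection(bed)
    expect_true(all(circ$r <= max(sphereRadii(bed)) + 1e-12))
  }
})

test_that("physical scaling anchors, filters and separates columns", {
  # hand-computed linear map: radii {0.5, 1, 0.25, 0.6} anchor the largest
  # to 200 um, giving {100, 200, 50, 120}; the 50 um circle falls below
  # the 80 um cutoff
  circ <- data.frame(cx = c(0, 5, 10, 0), cy = c(0, 5, 0, 5),
                     r = c(0.5, 1.0, 0.25, 0.6))
  layout <- scaleToPhysical(circ, chamberWidth = 4500, chamberHeight = 3000)
  cols <- layoutColumns(layout)
  expect_identical(nrow(cols), 3L)
  expect_setequal(round(cols$r), c(100, 200, 120))
  expect_true(all(cols$r >= 80 & cols$r <= 200))

  tiny <- data.frame(cx = c(0, 5, 10), cy = c(0, 0, 0),
                     r = c(0.1, 0.12, 1))   # two fall below 80 after scaling
  expect_error(scaleToPhysical(tiny), "degenerate")

  # crafted overlap: the smaller member is shrunk to tangency minus the gap
  over <- data.frame(cx = c(0, 1.5, 0), cy = c(0, 0, 3),
                     r = c(1.0, 0.8, 0.9))
  lay <- scaleToPhysical(over, rPhysMin = 20, rPhysMax = 200,
                         chamberWidth = 4000, chamberHeight = 4000,
                         gapUm = 5)
  cc <- layoutColumns(lay)
  d <- as.matrix(dist(cc[, c("cx", "cy")]))
  diag(d) <- Inf
  rim <- d - outer(cc$r, cc$r, "+")
  expect_gte(min(rim), 5 - 1e-6)
})

test_that("wall shear stress follows the plate formula and the duct series", {
  expect_identical(wallShearStress(0, height = 75), 0)
  expect_equal(wallShearStress(175, viscosity = 1e-3, height = 75), 0.014,
               tolerance = 1e-12)
  expect_equal(wallShearStress(350, height = 75),
               2 * wallShearStress(175, height = 75), tolerance = 1e-12)
  expect_error(wallShearStress(100, height = 0), "height")
  expect_error(wallShearStress(100, viscosity = 0, height = 75),
               "viscosity")

  # the duct pressure-drop route converges to the parallel-plate limit as
  # the aspect ratio grows; within 1% by W/H = 100
  plate <- wallShearStress(175, height = 75)
  duct100 <- wallShearStress(175, height = 75, width = 7500,
                             method = "duct")
  expect_lt(abs(duct100 - plate) / plate, 0.01)
  ratios <- sapply(c(5, 10, 50, 100, 500), function(a)
    wallShearStress(175, height = 75, width = 75 * a, method = "duct"))
  expect_true(all(diff(abs(ratios - plate)) < 0))
})
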