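test_that("ground truths are reproducible, connected and consistent", {
  sim <- smallExperiment(seed = 4, noise = FALSE)
  tess <- sim$tessellation

  t1 <- makeGroundTruth(tess, seed = 9)
  t2 <- makeGroundTruth(tess, seed = 9)
  expect_identical(t1, t2)

  blocked <- which(t1$flow == "blocked")
  expect_equal(length(blocked), round(0.4 * nRegions(tess)))
  # blocked set forms one connected patch
  adj <- regionAdjacency(tess)
  comp <- blocked[1]
  repeat {
    nb <- which(apply(adj[comp, , drop = FALSE], 2, any))
    grown <- union(comp, intersect(nb, blocked))
    if (length(grown) == length(comp)) break
    comp <- grown
  }
  expect_setequal(comp, blocked)
  # every open region keeps a flow path to inlet and outlet
  open <- t1$flow == "open"
  expect_identical(soilchip:::flowConnectedOpen(tess, open), open)
})

test_that("mutant occupancy honors the blocked:open odds in expectation", {
  sim <- smallExperiment(seed = 4, noise = FALSE)
  tess <- sim$tessellation
  nb <- no <- kb <- ko <- 0
  for (seed in 1:4) {
    tr <- makeGroundTruth(tess, seed = seed)
    b <- tr$flow == "blocked"
    nb <- nb + sum(b); no <- no + sum(!b)
    kb <- kb + sum(tr$mut[b]); ko <- ko + sum(tr$mut[!b])
  }
  expect_gt(nb + no, 200)
  pB <- kb / nb; pO <- ko / no
  expect_lt(abs(pB - 0.75), 4 * sqrt(0.75 * 0.25 / nb))
  expect_lt(abs(pO - 0.15), 4 * sqrt(0.15 * 0.85 / no))
  # empirical occupancy ratio consistent with 5:1
  expect_gt(pB / pO, 3)
})

test_that("scenes with no occupancy produce no positive calls", {
  sim <- smallExperiment(seed = 6, noise = FALSE)
  tess <- sim$tessellation
  truth0 <- sim$truth
  truth0$wt <- FALSE
  truth0$mut <- FALSE
  sc <- renderChamberScene(tess, truth0, noise = FALSE)
  mg <- regionMeanIntensity(sc$gfp, tess)
  expect_warning(calls <- callOccupancy(mg, "otsu"), "identical")
  expect_false(any(calls))
})

test_that("fully occupied noise-free scenes are recovered completely", {
  sim <- smallExperiment(seed = 6, noise = FALSE)
  tess <- sim$tessellation
  truth1 <- sim$truth
  truth1$wt <- TRUE
  sc <- renderChamberScene(tess, truth1, noise = FALSE, seed = 2)
  res <- analyzeChamberImages(sc$gfp, sc$mcherry, sim$beads,
                              columns = columnsFromLayout(sim$layout, 5),
                              umPerPx = 5)
  expect_true(all(res$calls$wt_call))
})

test_that("bead stacks are confined to open corridors", {
  sim <- smallExperiment(seed = 4, noise = FALSE)
  tess <- sim$tessellation
  truth <- sim$truth

  # streak pixels never fall in a blocked region's effective mask
  integ <- integrateBeadFrames(sim$beads)
  blockedIds <- which(truth$flow == "blocked")
  inBlocked <- matrix(tess@regionMap %in% blockedIds, nrow(integ)) &
    !tess@columnMask
  expect_true(all(integ[inBlocked] == 5))   # background only

  # all-blocked truth: a warning and zero streaks
  tb <- truth
  tb$flow[] <- "blocked"
  expect_warning(stk <- renderBeadStack(tess, tb, noise = FALSE, seed = 1),
                 "no open path")
  expect_true(all(stk == 5))

  # all-open truth: every region's coverage exceeds the flow threshold
  to <- truth
  to$flow[] <- "open"
  stk2 <- renderBeadStack(tess, to, noise = FALSE, seed = 1)
  fl <- scoreFlow(integrateBeadFrames(stk2), tess)
  expect_true(all(fl == "open"))

  # noise-free stacks recover the generated truth exactly
  fl2 <- scoreFlow(integ, tess)
  expect_identical(as.character(fl2), as.character(truth$flow))
})

test_that("competition sampling follows the selection model", {
  # hand evaluation of a * f0 * (1 - f0)
  rec <- sampleCompetition(0.5, regime = "uniform_positive", a = 0.8,
                           noiseSd = 0)
  expect_equal(rec$f72 - rec$f0, 0.2, tolerance = 1e-12)

  # sign change around the critical frequency
  f0 <- c(0.2, 0.4, 0.59, 0.61, 0.8)
  rec2 <- sampleCompetition(f0, a = 1, fc = 0.6, noiseSd = 0)
  df <- rec2$f72 - rec2$f0
  expect_true(all(df[f0 < 0.6] > 0))
  expect_true(all(df[f0 > 0.6] < 0))

  # absorbing limits: df vanishes as f0 approaches 0 or 1
  lim <- sampleCompetition(c(1e-6, 1 - 1e-6), a = 1, fc = 0.6, noiseSd = 0)
  expect_lt(max(abs(lim$f72 - lim$f0)), 1e-6)

  # bounds always hold with noise
  big <- sampleCompetition(runif(500, 0.01, 0.99), a = 1, fc = 0.6,
                           noiseSd = 0.2, seed = 8)
  expect_true(all(big$f72 >= 0 & big$f72 <= 1))
  expect_true(all(big$f72 - big$f0 <= 1 - big$f0 + 1e-12))

  expect_error(sampleCompetition(c(0.5, 1)), "strictly")
})

test_that("growth curves are logistic with recoverable maximum slope", {
  g <- sampleGrowthCurve(r = 0.25, K = 1, od0 = 0.01, dtMin = 30,
                         tEndHr = 60, noiseSd = 0)
  expect_equal(g$od600[1], 0.01, tolerance = 1e-12)
  expect_equal(tail(g$od600, 1), 1, tolerance = 1e-3)

  # analytic maximum slope on the sampled grid
  gridMax <- max(0.25 * g$od600 * (1 - g$od600 / 1))
  est <- maxGrowthRate(g$t_hr, g$od600, window = 5)
  expect_lt(abs(est - gridMax) / gridMax, 0.02)

  expect_error(sampleGrowthCurve(noiseSd = -1), "noiseSd")
})

test_that("generation is bit-reproducible under a fixed seed", {
  a <- smallExperiment(seed = 12)
  b <- smallExperiment(seed = 12)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$mcherry, b$mcherry)
  expect_identical(a$beads, b$beads)
  expect_identical(a$truth, b$truth)
})
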