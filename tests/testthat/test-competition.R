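test_that("frequency changes are validated and computed", {
  rec <- data.frame(f0 = c(0.5, 0.3, 0.7), f72 = c(0.5, 1.0, 0.6))
  out <- frequencyChange(rec)
  expect_equal(out$df, c(0, 0.7, -0.1))
  expect_true(all(out$df <= 1 - out$f0 + 1e-12))
  expect_error(frequencyChange(data.frame(f0 = 0.5, f72 = 1.2)), "f72")
  expect_error(frequencyChange(data.frame(f0 = 0, f72 = 0.5)), "f0")
})

test_that("selection fits classify regimes and locate the crossover", {
  f0 <- seq(0.1, 0.9, length.out = 30)

  pos <- sampleCompetition(f0, regime = "uniform_positive", a = 0.6,
                           noiseSd = 0)
  fitPos <- fitSelectionFunction(pos, nBoot = 100, seed = 1)
  expect_identical(fitPos@regime, "uniform_positive")
  expect_true(is.na(fitPos@fcHat))

  neg <- pos
  neg$f72 <- pmax(0, pos$f0 - 0.6 * pos$f0 * (1 - pos$f0))
  fitNeg <- fitSelectionFunction(neg, nBoot = 100, seed = 1)
  expect_identical(fitNeg@regime, "uniform_negative")

  nfd <- sampleCompetition(f0, a = 1, fc = 0.6, noiseSd = 0.03, seed = 5)
  fit <- fitSelectionFunction(nfd, seed = 5)
  expect_identical(fit@regime, "negative_freq_dependent")
  expect_lt(abs(fit@fcHat - 0.6), 0.1)
  expect_true(fit@ci[1] < fit@fcHat && fit@fcHat < fit@ci[2])

  # invariance to record order and duplication
  shuf <- nfd[sample(nrow(nfd)), ]
  fitShuf <- fitSelectionFunction(shuf, nBoot = 50, seed = 2)
  expect_equal(fitShuf@fcHat, fit@fcHat, tolerance = 1e-9)
  dup <- rbind(nfd, nfd)
  fitDup <- fitSelectionFunction(dup, nBoot = 50, seed = 2)
  expect_identical(fitDup@regime, fit@regime)
  expect_equal(fitDup@fcHat, fit@fcHat, tolerance = 1e-9)

  expect_error(fitSelectionFunction(nfd[1:5, ]), "at least 8")
  narrow <- sampleCompetition(seq(0.4, 0.6, length.out = 10), a = 1,
                              fc = 0.6, noiseSd = 0)
  expect_error(fitSelectionFunction(narrow), "span")
})

test_that("critical-frequency recovery matches the generator", {
  # the generating model df = a f0 (1-f0)(fc - f0) lies in the fitted
  # basis, so noise-free recovery is exact
  f0 <- seq(0.1, 0.9, length.out = 30)
  exact <- sampleCompetition(f0, a = 1, fc = 0.6, noiseSd = 0)
  fit0 <- fitSelectionFunction(exact, nBoot = 50, seed = 3)
  expect_equal(fit0@fcHat, 0.6, tolerance = 1e-6)

  # with replicate noise, the generating fc lies inside the bootstrap CI
  # in most seeded experiments
  hits <- 0
  for (i in 1:20) {
    rec <- sampleCompetition(f0, a = 1, fc = 0.6, noiseSd = 0.03,
                             seed = 300 + i)
    f <- fitSelectionFunction(rec, nBoot = 300, seed = 300 + i)
    if (all(is.finite(f@ci)) && f@ci[1] <= 0.6 && 0.6 <= f@ci[2])
      hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("maximum growth rate is a windowed slope with invariances", {
  t_ <- seq(0, 10, by = 0.5)
  expect_equal(maxGrowthRate(t_, 0.01 * t_), 0.01, tolerance = 1e-12)
  expect_equal(maxGrowthRate(t_, 0.01 * t_, window = 9), 0.01,
               tolerance = 1e-12)
  expect_equal(maxGrowthRate(t_, rep(0.3, length(t_))), 0)

  g <- sampleGrowthCurve(r = 0.25, K = 0.9, od0 = 0.01, dtMin = 30,
                         tEndHr = 60, noiseSd = 0)
  gridMax <- max(0.25 * g$od600 * (1 - g$od600 / 0.9))
  expect_lt(abs(maxGrowthRate(g$t_hr, g$od600) - gridMax) / gridMax, 0.02)

  # shift invariance in OD, equivariance in time units
  expect_equal(maxGrowthRate(g$t_hr, g$od600 + 0.05),
               maxGrowthRate(g$t_hr, g$od600), tolerance = 1e-12)
  expect_equal(maxGrowthRate(g$t_hr * 60, g$od600),
               maxGrowthRate(g$t_hr, g$od600) / 60, tolerance = 1e-12)

  expect_error(maxGrowthRate(1:3, 1:3, window = 5), "window")
  expect_error(maxGrowthRate(c(1, 1, 2, 3, 4), rep(1, 5)), "increasing")
})

test_that("effluent frequencies are simple count ratios", {
  expect_equal(effluentFrequency(50, 50), 0.5)
  expect_equal(effluentFrequency(30, 90), 0.25)
  expect_equal(effluentFrequency(100, 0), 1)
  expect_error(effluentFrequency(0, 0), "undefined")
  expect_error(effluentFrequency(-1, 5), "non-negative")
})
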