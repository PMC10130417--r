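# Synthetic-data generator: point patterns, docking, rendering, bleaching.

test_that("protein surfaces are Poisson with the requested density", {
  cfg <- simulationConfig(fieldSize = 10, seed = 1L)
  expect_equal(nrow(simulateProteinSurface(0, cfg)@points), 0L)
  expect_error(simulateProteinSurface(-1, cfg), "density")
  # Poisson moments over 200 seeds at rho = 1 on a 100 um^2 field
  counts <- vapply(1:200, function(s) {
    c2 <- cfg; c2@seed <- s
    nrow(simulateProteinSurface(1, c2)@points)
  }, 0L)
  expect_equal(mean(counts), 100, tolerance = 0.05)
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.8); expect_lt(disp, 1.2)
})

test_that("simulation is a pure function of config and seed", {
  cfg <- quickConfig(99L, fieldSize = 10)
  a <- simulateProteinSurface(0.5, cfg)
  b <- simulateProteinSurface(0.5, cfg)
  expect_identical(a@points, b@points)
  stA <- renderImageStack(list(p = a), cfg)
  stB <- renderImageStack(list(p = b), cfg)
  expect_identical(stA@channels, stB@channels)
  trA <- simulateBleachTrace(3, 5, 0.2, 100L, noiseSd = 1, seed = 5L)
  trB <- simulateBleachTrace(3, 5, 0.2, 100L, noiseSd = 1, seed = 5L)
  expect_identical(trA, trB)
})

test_that("dimer fraction controls multiplicity", {
  cfg <- simulationConfig(fieldSize = 30, seed = 2L)
  surf <- simulateProteinSurface(1, cfg, dimerFraction = 0.5)
  f <- mean(surf@multiplicity == 2L)
  n <- length(surf@multiplicity)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  expect_error(simulateProteinSurface(1, cfg, dimerFraction = 2), "dimerFraction")
})

test_that("vesicle docking respects occupancy and site geometry", {
  cfg <- simulationConfig(fieldSize = 30, seed = 3L)
  surf <- simulateProteinSurface(1, cfg)
  expect_equal(nrow(simulateVesicleBinding(surf, langmuirModel(1), 0, cfg)@positions), 0L)
  # half-saturation: V = Kd, alpha = 1
  ves <- simulateVesicleBinding(surf, langmuirModel(kd = 1), 1000, cfg)
  n <- nrow(surf@points)
  expect_lt(abs(nrow(ves@positions) / n - 0.5), 3 * sqrt(0.25 / n))
  expect_error(simulateVesicleBinding(surf, hillModel(1, 1, 1), 10, cfg),
               "LangmuirModel, CooperativeModel")
  # every bound vesicle lies within reach of a protein
  mC <- cooperativeModel(kd1 = 1, kd2 = 0.01, d = 0.3, alpha = 1)
  vC <- simulateVesicleBinding(surf, mC, 100, cfg)
  if (nrow(vC@positions)) {
    dmin <- vapply(seq_len(nrow(vC@positions)), function(i) {
      min(sqrt((surf@points[, 1] - vC@positions[i, 1])^2 +
               (surf@points[, 2] - vC@positions[i, 2])^2))
    }, 0)
    expect_true(all(dmin <= 0.3 + 1e-9))
  }
})

test_that("geometrically isolated fraction matches exp(-rho pi d^2)", {
  for (par in list(c(0.5, 0.2), c(2, 0.1))) {
    rho <- par[1]; d <- par[2]
    fr <- vapply(1:30, function(s) {
      cfg <- simulationConfig(fieldSize = 20, seed = 1000L + s)
      surf <- simulateProteinSurface(rho, cfg)
      mean(classifyBindingSites(surf, d)$isolated)
    }, 0)
    lam <- rho * pi * d^2
    se <- sd(fr) / sqrt(length(fr))
    expect_lt(abs(mean(fr) - exp(-lam)), 3 * se + 0.005)
  }
})

test_that("pairing is mutual within reach and bookkeeping is exact", {
  cfg <- simulationConfig(fieldSize = 20, seed = 8L)
  surf <- simulateProteinSurface(2, cfg)
  cls <- classifyBindingSites(surf, 0.2)
  n <- nrow(surf@points)
  expect_equal(length(cls$singles) + 2 * nrow(cls$pairs), n)
  if (nrow(cls$pairs)) {
    dd <- sqrt(rowSums((surf@points[cls$pairs[, 1], , drop = FALSE] -
                        surf@points[cls$pairs[, 2], , drop = FALSE])^2))
    expect_true(all(dd <= 0.2))
  }
  # no point appears twice
  expect_false(anyDuplicated(c(cls$singles, c(cls$pairs))) > 0)
})

test_that("rendering conserves flux and honours the offset", {
  cfg <- simulationConfig(fieldSize = 5, frames = 2L, readNoiseSd = 0,
                          photonsPerFluorophore = 0, seed = 4L)
  st <- renderImageStack(list(p = NULL), cfg)
  expect_true(all(channelData(st, "p") == cfg@cameraOffset))
  # noiseless single emitter: total background-subtracted flux equals the
  # photon budget to 0.1%
  cfg2 <- simulationConfig(fieldSize = 5, frames = 1L, readNoiseSd = 0,
                           photonsPerFluorophore = 5000, seed = 4L)
  em <- data.frame(x = 2.5, y = 2.5, photons = 5000)
  st2 <- renderImageStack(list(p = em), cfg2, noise = FALSE)
  tot <- measureTotalIntensity(st2@channels$p[1, , ], cfg2@cameraOffset)
  expect_equal(tot, 5000, tolerance = 1e-3)
  # emitters outside the field are rejected
  expect_error(renderImageStack(list(p = data.frame(x = 9, y = 1, photons = 1)),
                                cfg2), "within the field")
  # undersampled PSF warns
  cfg3 <- simulationConfig(fieldSize = 5, pixelSize = 0.108,
                           psfSigma = 0.02, seed = 1L)
  expect_warning(renderImageStack(list(p = NULL), cfg3), "undersampled")
})

test_that("crosstalk mixes expected images at the configured coefficient", {
  beta <- matrix(c(1, 0.05, 0, 1), 2, byrow = TRUE)
  cfg <- simulationConfig(fieldSize = 6, frames = 1L, crosstalk = beta,
                          readNoiseSd = 0, photonsPerFluorophore = 2000,
                          seed = 6L)
  em <- data.frame(x = 3, y = 3, photons = 2000)
  st <- renderImageStack(list(a = em, b = NULL), cfg, noise = FALSE)
  fa <- sum(st@channels$a[1, , ] - cfg@cameraOffset)
  fb <- sum(st@channels$b[1, , ] - cfg@cameraOffset)
  expect_equal(fb / fa, 0.05, tolerance = 1e-6)
  # with noise, the bleed amplitude stays within 1% absolute over seeds
  ratios <- vapply(1:25, function(s) {
    c2 <- cfg; c2@seed <- 100L + s
    c2@frames <- 5L
    stn <- renderImageStack(list(a = em, b = NULL), c2)
    ia <- averageInitialFrames(stn, 5L, "a")
    ib <- averageInitialFrames(stn, 5L, "b")
    spotAmplitudeAt(ib, 3, 3, c2@pixelSize, c2@psfSigma) /
      spotAmplitudeAt(ia, 3, 3, c2@pixelSize, c2@psfSigma)
  }, 0)
  expect_lt(abs(mean(ratios) - 0.05), 0.01)
})

test_that("bleach traces step down by one fluorophore at a time", {
  tr1 <- simulateBleachTrace(1, 5, 0.5, 60L, noiseSd = 0, seed = 11L)
  expect_equal(unique(tr1), c(5, 0))
  expect_true(all(diff(tr1) <= 0))
  tr3 <- simulateBleachTrace(3, 5, 0.5, 60L, noiseSd = 0, seed = 12L)
  expect_equal(tr3[1], 15)
  expect_error(simulateBleachTrace(0, 5, 0.5), "nFluorophores")
  # order statistics: first of two exponentials has mean 1/(2r)
  r <- 0.5
  first <- vapply(1:3000, function(s) {
    tr <- simulateBleachTrace(2, 1, r, 200L, frameInterval = 0.05,
                              noiseSd = 0, seed = s)
    (which(diff(tr) < 0)[1] - 0.5) * 0.05  # mid-frame bleach time
  }, 0)
  se <- sd(first) / sqrt(length(first))
  expect_lt(abs(mean(first) - 1 / (2 * r)), 3 * se + 0.05)
})

test_that("binding time courses follow the first-order approach", {
  kin <- kineticModel(kon = 1e-4, koff = 2e-3, neq = 0.05)
  tc <- simulateBindingTimecourse(kin, 3, c(0, 60, 300, 900, 3600))
  expect_equal(tc@y[1], 0)
  expect_equal(tc@y[5], 0.05, tolerance = 1e-3)
  kobs <- 1e-4 * 3 + 2e-3
  half <- simulateBindingTimecourse(kin, 3, log(2) / kobs)
  expect_equal(half@y, 0.025)
  expect_error(simulateBindingTimecourse(kin, 3, c(5, 1)), "increasing")
  # Poisson counting noise preserves the mean
  tcN <- simulateBindingTimecourse(kin, 3, rep(3600, 50), area = 500,
                                   seed = 3L)
  expect_lt(abs(mean(tcN@y) - 0.05), 3 * sqrt(0.05 / 500 / 50))
})
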