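# Colocalization, crosstalk and per-class statistics.

test_that("matching is exact on identical and disjoint spot lists", {
  A <- data.frame(x = runif(50, 0, 20), y = runif(50, 0, 20))
  r <- matchSpots(A, A, matchRadius = 0.216, fieldArea = 400)
  expect_equal(r@fractionA, 1); expect_equal(r@fractionB, 1)
  expect_equal(r@nMatched, 50L)
  B <- A; B$x <- B$x + 5  # shifted far beyond the radius
  r2 <- matchSpots(A, B, matchRadius = 0.216, fieldArea = 400)
  expect_equal(r2@nMatched, 0L)
  expect_equal(r2@fractionA, 0)
})

test_that("matched counts are symmetric in channel order", {
  set.seed(31)
  A <- data.frame(x = runif(200, 0, 30), y = runif(200, 0, 30))
  B <- data.frame(x = runif(180, 0, 30), y = runif(180, 0, 30))
  ab <- matchSpots(A, B, 0.4, 900)
  ba <- matchSpots(B, A, 0.4, 900)
  expect_equal(ab@nMatched, ba@nMatched)
})

test_that("independent channels colocalize at the chance level", {
  set.seed(32)
  n <- 0L; matched <- 0L
  rhoB <- 0.3; r <- 0.216; area <- 1600
  for (i in 1:4) {
    A <- data.frame(x = runif(rhoB * area, 0, 40), y = runif(rhoB * area, 0, 40))
    B <- data.frame(x = runif(rhoB * area, 0, 40), y = runif(rhoB * area, 0, 40))
    m <- matchSpots(A, B, r, area)
    n <- n + m@nA; matched <- matched + m@nMatched
    expect_equal(m@chanceFraction, 1 - exp(-rhoB * pi * r^2), tolerance = 1e-12)
  }
  p <- 1 - exp(-rhoB * pi * r^2)
  expect_lt(abs(matched / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("crosstalk coefficients are recovered from pure species", {
  mkStack <- function(beta, seedA, seedB, rho = 0.1) {
    cfg <- simulationConfig(fieldSize = 25.92, frames = 5L,
                            photonsPerFluorophore = 300, crosstalk = beta,
                            seed = seedA)
    sA <- simulateProteinSurface(rho, cfg)
    stA <- renderImageStack(list(chA = sA, chB = NULL), cfg)
    cfgB <- cfg; cfgB@seed <- seedB
    sB <- simulateProteinSurface(rho, cfgB)
    stB <- renderImageStack(list(chA = NULL, chB = sB), cfgB)
    list(chA = stA, chB = stB, cfg = cfg)
  }
  # null recovery
  st0 <- mkStack(diag(2), 71L, 72L)
  b0 <- estimateCrosstalk(list(chA = st0$chA, chB = st0$chB), psfSigma = 0.13)
  expect_lt(abs(b0["chA", "chB"]), 0.005)
  expect_lt(abs(b0["chB", "chA"]), 0.005)
  # beta = 0.05 within +/- 0.01, and unmixing leaves < 1% residual
  beta <- matrix(c(1, 0.05, 0, 1), 2, byrow = TRUE)
  st <- mkStack(beta, 73L, 74L)
  bh <- estimateCrosstalk(list(chA = st$chA, chB = st$chB), psfSigma = 0.13)
  expect_lt(abs(bh["chA", "chB"] - 0.05), 0.01)
  # channel order does not matter
  bh2 <- estimateCrosstalk(list(chB = st$chB, chA = st$chA), psfSigma = 0.13)
  expect_equal(bh, bh2)
  corr <- correctCrosstalk(st$chA, bh, offset = 100, floor = FALSE)
  sl <- detectSpots(averageInitialFrames(st$chA, 5L, "chA"), 0.108, 0.13)
  sp <- spots(sl)
  resid <- spotAmplitudeAt(averageInitialFrames(corr, 5L, "chB"),
                           sp$x, sp$y, 0.108, 0.13)
  src <- spotAmplitudeAt(averageInitialFrames(corr, 5L, "chA"),
                         sp$x, sp$y, 0.108, 0.13)
  expect_lt(abs(median(resid / src, na.rm = TRUE)), 0.01)
  # insufficient spots
  sparse <- mkStack(diag(2), 75L, 76L, rho = 0.005)
  expect_error(estimateCrosstalk(list(chA = sparse$chA, chB = sparse$chB),
                                 psfSigma = 0.13), "insufficient")
})

test_that("unmixing inverts mixing exactly on noiseless stacks", {
  beta <- matrix(c(1, 0.3, 0.2, 1), 2, byrow = TRUE)
  cfg <- simulationConfig(fieldSize = 8, frames = 1L, readNoiseSd = 0,
                          crosstalk = beta, photonsPerFluorophore = 1000,
                          seed = 81L)
  emA <- data.frame(x = c(2, 6), y = c(2, 5), photons = 1000)
  emB <- data.frame(x = 4, y = 6, photons = 800)
  mixed <- renderImageStack(list(a = emA, b = emB), cfg, noise = FALSE)
  cfgI <- cfg; cfgI@crosstalk <- diag(2)
  pure <- renderImageStack(list(a = emA, b = emB), cfgI, noise = FALSE)
  un <- correctCrosstalk(mixed, beta, offset = cfg@cameraOffset)
  for (ch in c("a", "b"))
    expect_equal(channelData(un, ch), channelData(pure, ch),
                 tolerance = 1e-3)
  # identity matrix changes nothing
  same <- correctCrosstalk(mixed, diag(2), offset = cfg@cameraOffset)
  expect_equal(same@channels, mixed@channels, tolerance = 1e-12)
  expect_error(correctCrosstalk(mixed, matrix(1, 2, 2)), "invertible")
})

test_that("enrichment folds mirror fraction ratios with bootstrap CIs", {
  expect_equal(enrichmentFold(0.3, 0.3)$fold, 1)
  expect_equal(enrichmentFold(0.41, 0.10)$fold, 4.1)
  expect_error(enrichmentFold(0.3, 0), "positive")
  ef <- enrichmentFold(hitsTarget = 82, nTarget = 200, hitsControl = 20,
                       nControl = 200, seed = 3L)
  expect_equal(ef$fold, 4.1)
  expect_gt(ef$ci[1], 1)  # strong effect: CI excludes 1
})

test_that("vesicle-bound fractions separate site classes", {
  A <- data.frame(x = c(1, 2, 3, 4), y = rep(1, 4))
  AB <- data.frame(x = c(1, 2, 3, 4), y = rep(3, 4))
  none <- vesicleBoundFraction(data.frame(x = numeric(0), y = numeric(0)),
                               A, AB)
  expect_equal(unname(none), c(0, 0))
  onAB <- vesicleBoundFraction(AB, A, AB, matchRadius = 0.2)
  expect_equal(unname(onAB), c(0, 1))
  # simulator: pair sites outcompete monomer sites at kd2/kd1 = 1e-3
  set.seed(91)
  nS <- 60; nP <- 60
  singles <- cbind(runif(nS, 1, 19), runif(nS, 1, 9))
  pairA <- cbind(runif(nP, 1, 19), runif(nP, 11, 19))
  pts <- rbind(singles, pairA, pairA + 0.05)
  surf <- new("ProteinSurface", points = pts,
              multiplicity = rep(1L, nrow(pts)), density = nrow(pts) / 400,
              fieldSize = 20)
  model <- cooperativeModel(kd1 = 100, kd2 = 0.1, d = 0.1, alpha = 1)
  cfg <- simulationConfig(fieldSize = 20, seed = 92L)
  ves <- simulateVesicleBinding(surf, model, conc = 100, cfg)
  fr <- vesicleBoundFraction(
    data.frame(x = ves@positions[, 1], y = ves@positions[, 2]),
    data.frame(x = singles[, 1], y = singles[, 2]),
    data.frame(x = pairA[, 1] + 0.025, y = pairA[, 2] + 0.025),
    matchRadius = 0.2)
  expect_gte(fr[["coloc"]], 5 * max(fr[["aOnly"]], 0.02))
})

test_that("bound fractions express as 1:N molar ratios", {
  r <- ratiometricBoundFraction(0.07)
  expect_equal(r$ratioN, 14L)
  expect_equal(r$ratio, "1:14")
  expect_equal(ratiometricBoundFraction(0.5)$ratioN, 2L)
  expect_equal(ratiometricBoundFraction(1)$ratioN, 1L)
  expect_true(is.na(ratiometricBoundFraction(0)$ratioN))
  expect_error(ratiometricBoundFraction(1.2), "\\[0, 1\\]")
})

test_that("per-class intensity comparison has power and calibration", {
  set.seed(41)
  a <- rlnorm(100, log(100), 0.3)
  expect_error(intensityByClass(a, rep("x", 100)), "two classes")
  # identical distributions: p rarely small
  ps <- vapply(1:30, function(s) {
    set.seed(s)
    x <- rlnorm(200, log(100), 0.3)
    intensityByClass(x, rep(c("a", "b"), each = 100), nPerm = 400L,
                     seed = s)$p.value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.80)
  # 1.5x shifted class detected
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- c(rlnorm(100, log(100), 0.3), rlnorm(100, log(150), 0.3))
    intensityByClass(x, rep(c("a", "b"), each = 100), nPerm = 400L,
                     seed = s)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
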