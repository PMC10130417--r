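# Spot detection, counting and photometry.

test_that("frame averaging reduces noise as 1/sqrt(n)", {
  arr <- array(100, dim = c(10, 20, 20))
  st <- new("ImageStack", channels = list(p = arr), pixelSize = 0.108,
            frameInterval = 0.1)
  expect_true(all(averageInitialFrames(st, 10L, "p") == 100))
  expect_error(averageInitialFrames(st, 11L), "only 10")
  set.seed(1)
  arrN <- array(rnorm(10 * 50 * 50, 0, 2), dim = c(10, 50, 50))
  stN <- new("ImageStack", channels = list(p = arrN), pixelSize = 0.108,
             frameInterval = 0.1)
  expect_identical(averageInitialFrames(stN, 1L, "p"), arrN[1, , ])
  avg <- averageInitialFrames(stN, 10L, "p")
  expect_equal(sd(avg), 2 / sqrt(10), tolerance = 0.1)
})

test_that("blank fields yield no spots at a 5 sigma threshold", {
  zeros <- 0L
  for (s in 1:100) {
    set.seed(s)
    img <- matrix(100 + rnorm(128^2, 0, 2), 128)
    if (nSpots(detectSpots(img, 0.108, 0.13, k = 5)) == 0L) zeros <- zeros + 1L
  }
  expect_gte(zeros, 99L)
  expect_error(detectSpots(matrix(5, 4, 4), 0.108, 0.13), "degenerate")
})

test_that("a single emitter is localized to sub-pixel accuracy", {
  cfg <- simulationConfig(fieldSize = 5, frames = 10L,
                          photonsPerFluorophore = 62, seed = 21L)
  em <- data.frame(x = 2.531, y = 2.467, photons = 62)
  st <- renderImageStack(list(p = em), cfg)
  sl <- detectSpots(averageInitialFrames(st, 10L, "p"),
                    cfg@pixelSize, cfg@psfSigma)
  expect_equal(nSpots(sl), 1L)
  sp <- spots(sl)
  dpx <- sqrt((sp$x - 2.531)^2 + (sp$y - 2.467)^2) / cfg@pixelSize
  expect_lt(dpx, 0.5)
})

test_that("detection reaches the accuracy targets at SNR ~10", {
  tot <- c(matched = 0, truth = 0, det = 0)
  sqerr <- c(); nerr <- 0
  for (s in 1:3) {
    sc <- detectionScore(0.1, seed = 30L + s)
    tot <- tot + c(sc$matched, sc$nTruth, sc$nDet)
    if (nrow(sc$pairs)) {
      dd <- sc$pairs$distance / 0.108
      sqerr <- c(sqerr, dd^2)
    }
  }
  expect_gte(tot[["matched"]] / tot[["truth"]], 0.95)  # recall
  expect_gte(tot[["matched"]] / tot[["det"]], 0.95)    # precision
  # sub-pixel RMSE of matched localizations
  expect_lt(sqrt(mean(sqerr)), 0.25)
})

test_that("spot density undercounts above the diffraction ceiling", {
  fl <- renderField(3, seed = 41L, photons = 200)
  sl <- detectSpots(fl$img, fl$cfg@pixelSize, fl$cfg@psfSigma)
  truth <- nrow(fl$surf@points) / fl$cfg@fieldSize^2
  expect_lt(countSpotDensity(sl) / truth, 0.8)
})

test_that("spot density arithmetic", {
  sl <- new("SpotList",
            spots = data.frame(channel = "a", x = runif(1000, 0, 100),
                               y = runif(1000, 0, 100), amplitude = 1,
                               integrated = 1, sigma = 0.13),
            metadata = list())
  expect_equal(countSpotDensity(sl, 1e4), 0.1)
  expect_error(countSpotDensity(sl, 0), "positive")
  empty <- new("SpotList", spots = sl@spots[0, ], metadata = list())
  expect_equal(countSpotDensity(empty, 10), 0)
})

test_that("total intensity is linear in the emitter load", {
  cfg <- simulationConfig(fieldSize = 10, frames = 1L, readNoiseSd = 0,
                          photonsPerFluorophore = 1000, seed = 51L)
  blank <- renderImageStack(list(p = NULL), cfg, noise = FALSE)
  expect_equal(measureTotalIntensity(blank@channels$p[1, , ],
                                     cfg@cameraOffset), 0)
  em <- data.frame(x = runif(30, 1, 9), y = runif(30, 1, 9), photons = 1000)
  one <- renderImageStack(list(p = em), cfg, noise = FALSE)
  two <- renderImageStack(list(p = rbind(em, em)), cfg, noise = FALSE)
  i1 <- measureTotalIntensity(one@channels$p[1, , ], cfg@cameraOffset)
  i2 <- measureTotalIntensity(two@channels$p[1, , ], cfg@cameraOffset)
  expect_equal(i1, 30000, tolerance = 1e-3)
  expect_equal(i2, 2 * i1, tolerance = 1e-6)
})

test_that("VPI counting is thresholded and brightness-invariant", {
  cfg <- simulationConfig(fieldSize = 15, frames = 5L,
                          photonsPerFluorophore = 100, seed = 61L)
  set.seed(61)
  nB <- 25; nD <- 25
  bright <- data.frame(x = runif(nB, 1, 14), y = runif(nB, 1, 14),
                       photons = 500)
  dim_ <- data.frame(x = runif(nD, 1, 14), y = runif(nD, 1, 14),
                     photons = 100)
  st <- renderImageStack(list(p = rbind(bright, dim_)), cfg)
  img <- averageInitialFrames(st, 5L, "p")
  # threshold between the two intensity modes (5x apart)
  thr <- 250
  res <- countVPI(img, cfg@pixelSize, cfg@psfSigma, vpiThreshold = thr, k = 4)
  expect_lte(abs(res$count - nB) / nB, 0.05)
  # all spots below threshold -> zero counts
  resHi <- countVPI(img, cfg@pixelSize, cfg@psfSigma, vpiThreshold = 1e6)
  expect_equal(resHi$count, 0L)
  # doubling the brightness of above-threshold spots leaves the count as is
  bright2 <- bright; bright2$photons <- 1000
  st2 <- renderImageStack(list(p = rbind(bright2, dim_)), cfg)
  res2 <- countVPI(averageInitialFrames(st2, 5L, "p"), cfg@pixelSize,
                   cfg@psfSigma, vpiThreshold = thr, k = 4)
  expect_equal(res2$count, res$count)
})
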