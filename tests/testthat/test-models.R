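# Closed-form adsorption models and unit conversions.

test_that("particle concentrations convert to molar units", {
  # 2e9 particles/ml is ~3 pM at one significant figure
  expect_equal(signif(particlesPerMlToPM(2e9), 1), 3)
  expect_equal(particlesPerMlToPM(2e9), 2e9 * 1e3 / 6.02214076e23 * 1e12)
  expect_equal(particlesPerMlToPM(0), 0)
  # exact algebra: 6.022e11 /ml ~ 1 nM
  expect_equal(particlesPerMlToPM(6.022e11), 1000, tolerance = 1e-4)
  expect_error(particlesPerMlToPM(-1), "non-negative")
})

test_that("Langmuir model has its defining limits", {
  m <- langmuirModel(kd = 0.25, alpha = 1)
  expect_equal(langmuirNb(10, 0, m), 0)
  # half-saturation: V = Kd (0.25 nM = 250 pM)
  expect_equal(langmuirNb(10, 250, m), 5)
  # linear in density
  rho <- c(0.5, 7, 31)
  expect_equal(langmuirNb(2 * rho, 3, m), 2 * langmuirNb(rho, 3, m))
  expect_error(langmuirModel(kd = -1), "positive")
  expect_error(langmuirModel(kd = 1, alpha = 1.5), "alpha")
})

test_that("site densities follow the Poisson nearest-neighbour law", {
  # lambda = ln 2 makes exp(-lambda) = 1/2 exactly
  d <- 0.1
  rho <- log(2) / (pi * d^2)
  s <- siteDensities(rho, d)
  expect_equal(s$s1, rho / 2)
  expect_equal(s$s2, rho / 4)
  # small-density series: s1 -> rho, s2 -> rho^2 pi d^2 / 2
  r0 <- 1e-6
  s0 <- siteDensities(r0, d)
  expect_equal(s0$s1, r0, tolerance = 1e-4)
  expect_equal(s0$s2, r0^2 * pi * d^2 / 2, tolerance = 1e-4)
})

test_that("site bookkeeping identity s1 + 2 s2 = rho holds to machine precision", {
  set.seed(42)
  rho <- runif(1000, 0, 50)
  d <- runif(1000, 0.02, 0.5)
  s <- siteDensities(rho, d)
  expect_equal(s$s1 + 2 * s$s2, rho, tolerance = 1e-12)
})

test_that("cooperative model reduces to Langmuir and is super-linear", {
  # geometric limit d -> 0: only monomeric sites remain
  mC <- cooperativeModel(kd1 = 5, kd2 = 0.01, d = 1e-6, alpha = 1)
  mL <- langmuirModel(kd = 5, alpha = 1)
  rho <- c(0.5, 5, 40)
  expect_equal(cooperativeNb(rho, 3, mC), langmuirNb(rho, 3, mL),
               tolerance = 1e-6)
  # nesting: with Kd2 = Kd1 and the pair term re-expanded with s1 + 2 s2
  # weighting, the Langmuir form is recovered exactly
  s <- siteDensities(rho, 0.1)
  occ <- (3e-3) / (3e-3 + 5)
  expect_equal((s$s1 + 2 * s$s2) * occ, langmuirNb(rho, 3, mL))
  # low-density algebra: Nb ~ alpha V (rho/Kd1 + rho^2 pi d^2/(2 Kd2))
  m <- cooperativeModel(kd1 = 130, kd2 = 0.09, d = 0.1, alpha = 1)
  r0 <- 1e-3
  v <- 3e-3  # 3 pM in nM
  approxNb <- v * (r0 / 130 + r0^2 * pi * 0.01 / (2 * 0.09))
  expect_equal(cooperativeNb(r0, 3, m), approxNb, tolerance = 1e-3)
  # super-linear density dependence with the NK constants
  expect_gt(maxLogLogSlope(m, conc = 3, rhoRange = c(0.5, 40)), 1.5)
})

test_that("Hill model matches brute-force evaluation and reductions", {
  m <- hillModel(nmax = 0.1, khalf = 2e9, n = 2.2)
  expect_equal(hillN(2e9, m), 0.05)
  # n = 1 is the Langmuir form in concentration
  m1 <- hillModel(nmax = 0.1, khalf = 2e9, n = 1)
  v <- c(1e8, 2e9, 7e9)
  expect_equal(hillN(v, m1), 0.1 * v / (v + 2e9))
  # ratio N(2K)/N(K) at n = 2.2, brute arithmetic oracle
  oracle <- (2^2.2 / (1 + 2^2.2)) / (1 / 2)
  expect_equal(hillN(4e9, m) / hillN(2e9, m), oracle, tolerance = 1e-12)
})

test_that("inhibition and kinetic curves hit their anchor points", {
  ih <- inhibitionModel(n0 = 0.06, nbg = 0.005, ic50 = 1, h = 1.3)
  expect_equal(inhibitionN(0, ih), 0.06)
  expect_equal(inhibitionN(1, ih), (0.06 + 0.005) / 2)
  expect_equal(inhibitionN(1e9, ih), 0.005, tolerance = 1e-6)
  expect_true(all(diff(inhibitionN(c(0.01, 0.1, 1, 10, 100), ih)) < 0))
  kin <- kineticModel(kon = 1e-4, koff = 1e-3, neq = 0.05)
  expect_equal(kineticN(0, kin, 3), 0)
  kobs <- 1e-4 * 3 + 1e-3
  expect_equal(kineticN(log(2) / kobs, kin, 3), 0.025)
  expect_equal(kineticN(1e6, kin, 3), 0.05)
  # equilibration within 15 min when 1/kobs = 3 min
  kin2 <- kineticModel(kon = 0, koff = 1 / 180, neq = 1)
  expect_gt(kineticN(900, kin2, 0) / 1, 0.99)
  # no drive, no binding
  kin3 <- kineticModel(kon = 1e-4, koff = 0, neq = 0.05)
  expect_equal(kineticN(c(0, 10, 1e4), kin3, 0), c(0, 0, 0))
})

test_that("all models conserve sites and respond monotonically", {
  set.seed(7)
  rho <- sort(runif(20, 0, 40))
  vv <- sort(runif(20, 0, 5000))
  for (i in 1:10) {
    mL <- langmuirModel(kd = 10^runif(1, -2, 3), alpha = runif(1, 0.2, 1))
    mC <- cooperativeModel(kd1 = 10^runif(1, 0, 3), kd2 = 10^runif(1, -2, 0),
                           d = runif(1, 0.05, 0.3), alpha = runif(1, 0.2, 1))
    nbL <- langmuirNb(rho, 500, mL)
    nbC <- cooperativeNb(rho, 500, mC)
    expect_true(all(nbL >= 0 & nbL <= mL@alpha * rho + 1e-12))
    expect_true(all(nbC >= 0 & nbC <= mC@alpha * rho + 1e-12))
    expect_true(all(diff(nbL) >= 0) && all(diff(nbC) >= 0))
    expect_true(all(diff(langmuirNb(10, vv, mL)) >= 0))
    expect_true(all(diff(cooperativeNb(10, vv, mC)) >= 0))
  }
})

test_that("predictNb dispatches to the matching closed form", {
  expect_equal(predictNb(langmuirModel(0.25), c(1, 10), conc = 3),
               langmuirNb(c(1, 10), 3, langmuirModel(0.25)))
  expect_equal(predictNb(hillModel(0.1, 2e9, 2.2), 1e9),
               hillN(1e9, hillModel(0.1, 2e9, 2.2)))
  expect_equal(predictNb(inhibitionModel(0.06, 0, 1, 1), 2),
               inhibitionN(2, inhibitionModel(0.06, 0, 1, 1)))
})
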