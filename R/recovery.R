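# Scenario presets and parameter-recovery experiments.

# Ground-truth presets shared by the table generator, the fixture writer
# and the recovery experiments. Vesicle concentration 3 pM (~2e9
# particles/ml), densities spanning the accessible surface range up to
# ~40 molecules/um^2, 5 technical replicates with 10% multiplicative
# measurement noise.
.scenarioTruth <- function(scenario) {
  switch(scenario,
    "u937-like-linear" = list(
      model = langmuirModel(kd = 0.25, alpha = 1),
      concPM = 3, x = c(0.5, 1, 2, 5, 10, 20, 40), xKind = "density",
      nRep = 5L, noise = 0.1),
    "nk-like-cooperative" = list(
      model = cooperativeModel(kd1 = 130, kd2 = 0.09, d = 0.1, alpha = 1),
      concPM = 3, x = c(0.5, 1, 2, 5, 10, 20, 40), xKind = "density",
      nRep = 5L, noise = 0.1),
    "hill-concentration" = list(
      model = hillModel(nmax = 0.1, khalf = 2e9, n = 2.2),
      concPM = NA, x = logSeq(2.5e8, 8e9, 6), xKind = "concentration",
      nRep = 5L, noise = 0.1),
    "inhibition-dose-response" = list(
      model = inhibitionModel(n0 = 0.06, nbg = 0.005, ic50 = 1, h = 1),
      concPM = NA, x = logSeq(0.01, 100, 7), xKind = "dose",
      nRep = 5L, noise = 0.1),
    stop(sprintf("unknown scenario '%s'", scenario))
  )
}

#' Generate a synthetic binding curve from a named scenario
#'
#' Draws one replicated curve from the scenario's ground-truth model with
#' multiplicative Gaussian measurement noise (sd = `noise` x true value,
#' floored at 0), emulating the replicate scatter of repeated TIRF fields.
#'
#' @param scenario one of "u937-like-linear", "nk-like-cooperative",
#'   "hill-concentration", "inhibition-dose-response".
#' @param seed integer seed.
#' @param nRep optional override of the scenario replicate count.
#' @param noise optional override of the scenario noise CV.
#' @return a [BindingCurve-class]; the truth is attached as attribute
#'   `truth`.
#' @export
simulateBindingCurve <- function(scenario, seed = 1L, nRep = NULL,
                                 noise = NULL) {
  tr <- .scenarioTruth(scenario)
  if (!is.null(nRep)) tr$nRep <- as.integer(nRep)
  if (!is.null(noise)) tr$noise <- noise
  mu <- predictNb(tr$model, rep(tr$x, each = tr$nRep), conc = tr$concPM)
  y <- withSubSeed(seed, paste0("curve-", scenario), {
    pmax(mu * (1 + stats::rnorm(length(mu), 0, tr$noise)), 0)
  })
  cv <- bindingCurve(rep(tr$x, each = tr$nRep), y, tr$xKind, conc = tr$concPM)
  attr(cv, "truth") <- tr$model
  cv
}

#' Parameter-recovery experiment over seeded runs
#'
#' Repeatedly generates a scenario curve, fits the matching model and
#' summarizes recovery: per-parameter bias and RMSE (on the log10 scale for
#' equilibrium constants and half-saturation points), the fraction of runs
#' with both log-constants within +/- `tolLog` of truth, and bootstrap CI
#' coverage when `nBoot` > 0.
#'
#' In "image" mode each run exercises the full pipeline on a reduced field:
#' protein surfaces are simulated at each density, vesicles docked under
#' the truth model, the vesicle channel rendered, spots detected and
#' thresholded into VPI counts, and the resulting measured curve is
#' summarized by its maximum log-log slope (super-linearity).
#'
#' @param scenario scenario name (see [simulateBindingCurve()]).
#' @param nRuns number of seeded runs.
#' @param seed integer top-level seed.
#' @param mode "table" (model-level curves) or "image" (render + detect).
#' @param nBoot bootstrap draws per run (0 = none, the default here).
#' @param tolLog half-width of the log10 recovery band (default 0.3).
#' @param fieldSize field side for image mode (um).
#' @param nRep,noise optional overrides of the scenario replicate count and
#'   noise CV (see [simulateBindingCurve()]).
#' @return list with `summary` (data.frame per parameter), `estimates`
#'   (matrix runs x parameters), `withinTol` fraction, and for image mode
#'   `maxSlopes` per run.
#' @export
recoveryExperiment <- function(scenario, nRuns = 100L, seed = 1L,
                               mode = c("table", "image"), nBoot = 0L,
                               tolLog = 0.3, fieldSize = 25.92,
                               nRep = NULL, noise = NULL) {
  mode <- match.arg(mode)
  tr <- .scenarioTruth(scenario)
  kind <- switch(class(tr$model), LangmuirModel = "langmuir",
                 CooperativeModel = "cooperative", HillModel = "hill",
                 InhibitionModel = "ic50")
  logPars <- c("kd", "kd1", "kd2", "khalf", "ic50")
  truthNat <- switch(kind,
    langmuir = c(kd = tr$model@kd),
    cooperative = c(kd1 = tr$model@kd1, kd2 = tr$model@kd2),
    hill = c(nmax = tr$model@nmax, khalf = tr$model@khalf, n = tr$model@n),
    ic50 = c(n0 = tr$model@n0, nbg = tr$model@nbg, ic50 = tr$model@ic50,
             h = tr$model@h))
  if (mode == "image") {
    maxSlopes <- rep(NA_real_, nRuns)
    failures <- 0L
    for (r in seq_len(nRuns)) {
      sl <- tryCatch(.imageModeRun(tr, vpiSubSeed(seed, paste0("img", r)),
                                   fieldSize),
                     error = function(e) NA_real_)
      if (is.na(sl)) failures <- failures + 1L else maxSlopes[r] <- sl
    }
    return(list(scenario = scenario, mode = mode, maxSlopes = maxSlopes,
                failures = failures))
  }
  est <- matrix(NA_real_, nRuns, length(truthNat),
                dimnames = list(NULL, names(truthNat)))
  covered <- matrix(NA, nRuns, length(truthNat),
                    dimnames = list(NULL, names(truthNat)))
  failures <- 0L
  for (r in seq_len(nRuns)) {
    runSeed <- vpiSubSeed(seed, paste0("run", r))
    cv <- simulateBindingCurve(scenario, seed = runSeed, nRep = nRep,
                               noise = noise)
    fr <- tryCatch(fitModel(cv, kind, nBoot = nBoot, seed = runSeed),
                   error = function(e) NULL)
    if (is.null(fr) || !fr@converged) { failures <- failures + 1L; next }
    est[r, names(fr@estimates)] <- fr@estimates
    if (nBoot > 0L && nrow(fr@ci)) {
      for (pn in rownames(fr@ci))
        covered[r, pn] <- truthNat[pn] >= fr@ci[pn, 1] &
                          truthNat[pn] <= fr@ci[pn, 2]
    }
  }
  summ <- do.call(rbind, lapply(names(truthNat), function(pn) {
    e <- est[, pn]
    if (pn %in% logPars) {
      err <- log10(e) - log10(truthNat[pn]); scale <- "log10"
    } else {
      err <- e - truthNat[pn]; scale <- "natural"
    }
    data.frame(parameter = pn, scale = scale, truth = truthNat[pn],
               bias = mean(err, na.rm = TRUE),
               rmse = sqrt(mean(err^2, na.rm = TRUE)),
               coverage = mean(covered[, pn], na.rm = TRUE),
               row.names = NULL)
  }))
  logNames <- intersect(names(truthNat), logPars)
  withinTol <- if (length(logNames)) {
    ok <- rep(TRUE, nRuns)
    for (pn in logNames)
      ok <- ok & abs(log10(est[, pn]) - log10(truthNat[pn])) <= tolLog
    mean(ok, na.rm = TRUE)
  } else NA_real_
  list(scenario = scenario, mode = mode, summary = summ, estimates = est,
       withinTol = withinTol, failures = failures)
}

# One image-level pipeline run: returns the measured curve's max log-log
# slope of detected VPI density vs realized protein density.
.imageModeRun <- function(tr, seed, fieldSize) {
  xs <- tr$x
  dens <- rep(NA_real_, length(xs))
  counts <- rep(NA_real_, length(xs))
  for (i in seq_along(xs)) {
    cfg <- simulationConfig(fieldSize = fieldSize, frames = 5L,
                            photonsPerFluorophore = 300,
                            seed = vpiSubSeed(seed, paste0("lvl", i)))
    surf <- simulateProteinSurface(xs[i], cfg)
    ves <- simulateVesicleBinding(surf, tr$model, tr$concPM, cfg)
    stack <- renderImageStack(list(vesicle = ves), cfg)
    img <- averageInitialFrames(stack, 5L, "vesicle")
    res <- countVPI(img, cfg@pixelSize, cfg@psfSigma, vpiThreshold = 1,
                    k = 5)
    dens[i] <- nrow(surf@points) / fieldSize^2
    counts[i] <- res$density
  }
  ok <- counts > 0 & dens > 0
  if (sum(ok) < 3L) return(NA_real_)
  max(diff(log(counts[ok])) / diff(log(dens[ok])))
}
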