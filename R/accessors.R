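# Accessors and show methods.

#' @describeIn SpotList-class spot table accessor.
#' @param object a SpotList.
#' @export
setMethod("spots", "SpotList", function(object) object@spots)

#' @describeIn SpotList-class number of spots.
#' @export
setMethod("nSpots", "SpotList", function(object) nrow(object@spots))

#' @describeIn DensityCalibration-class slope accessor.
#' @export
setMethod("calSlope", "DensityCalibration", function(object) object@slope)

#' @describeIn DensityCalibration-class intercept accessor.
#' @export
setMethod("calIntercept", "DensityCalibration", function(object) object@intercept)

#' @describeIn BleachAnalysis-class step-count accessor.
#' @export
setMethod("nSteps", "BleachAnalysis", function(object) object@nSteps)

#' @describeIn ImageStack-class pixel array of one channel.
#' @param channel channel name or index.
#' @export
setMethod("channelData", "ImageStack", function(object, channel = 1L) {
  object@channels[[channel]]
})

#' @describeIn ImageStack-class channel names.
#' @export
setMethod("channelNames", "ImageStack", function(object) names(object@channels))

#' Point estimates of a fit
#' @param object a [FitResult-class].
#' @param ... ignored.
#' @return named numeric vector on the natural scale.
#' @export
setMethod("coef", "FitResult", function(object, ...) object@estimates)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@fieldSize, "um field,",
      object@pixelSize, "um/px, PSF sigma", object@psfSigma, "um\n")
  cat(" ", object@frames, "frames @", object@frameInterval, "s;",
      object@photonsPerFluorophore, "photons/fluorophore/frame;",
      "offset", object@cameraOffset, "; read noise", object@readNoiseSd, "\n")
  cat("  channels:", nrow(object@crosstalk), "; seed:", object@seed, "\n")
})

setMethod("show", "ProteinSurface", function(object) {
  cat("ProteinSurface:", nrow(object@points), "molecules on a",
      object@fieldSize, "um field (nominal density", object@density,
      "/um^2)\n")
  if (length(object@multiplicity))
    cat("  multimers:", sum(object@multiplicity > 1L), "\n")
})

setMethod("show", "VesicleField", function(object) {
  cat("VesicleField:", nrow(object@positions), "bound vesicles (",
      sum(object@siteClass == "paired"), "on paired sites )\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("ImageStack:", length(object@channels), "channel(s) [",
      paste(names(object@channels), collapse = ", "), "],",
      d[1], "frames,", d[2], "x", d[3], "px @", object@pixelSize, "um/px\n")
})

setMethod("show", "SpotList", function(object) {
  cat("SpotList:", nrow(object@spots), "spots")
  if (!is.null(object@metadata$threshold))
    cat(" (threshold", signif(object@metadata$threshold, 4), "counts)")
  cat("\n")
})

setMethod("show", "DensityCalibration", function(object) {
  cat("DensityCalibration: I =", signif(object@slope, 6), "* rho +",
      signif(object@intercept, 6), "\n")
  cat("  built on rho in [", object@range[1], ",", object@range[2],
      "] spots/um^2; R^2 =", signif(object@diagnostics$r.squared, 4), "\n")
})

setMethod("show", "BleachAnalysis", function(object) {
  cat("BleachAnalysis:", object@nSteps, "bleaching step(s), step size",
      signif(object@stepSize, 4), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ColocalizationResult", function(object) {
  cat("ColocalizationResult:", object@nMatched, "matched of",
      object@nA, "(A) /", object@nB, "(B) within", object@matchRadius, "um\n")
  cat("  fractions: A", signif(object@fractionA, 4), "| B",
      signif(object@fractionB, 4), "| chance",
      signif(object@chanceFraction, 4), "\n")
})

setMethod("show", "LangmuirModel", function(object) {
  cat("LangmuirModel: Kd =", object@kd, "nM, alpha =", object@alpha, "\n")
})

setMethod("show", "CooperativeModel", function(object) {
  cat("CooperativeModel: Kd1 =", object@kd1, "nM, Kd2 =", object@kd2,
      "nM, reach d =", object@d, "um, alpha =", object@alpha, "\n")
})

setMethod("show", "HillModel", function(object) {
  cat("HillModel: Nmax =", object@nmax, ", Khalf =", object@khalf,
      ", n =", object@n, "\n")
})

setMethod("show", "InhibitionModel", function(object) {
  cat("InhibitionModel: N0 =", object@n0, ", Nbg =", object@nbg,
      ", IC50 =", object@ic50, "uM, h =", object@h, "\n")
})

setMethod("show", "KineticModel", function(object) {
  cat("KineticModel: kon =", object@kon, "/(pM s), koff =", object@koff,
      "/s, Neq =", object@neq, "\n")
})

setMethod("show", "BindingCurve", function(object) {
  cat("BindingCurve (", object@xKind, " axis): ",
      length(unique(object@x)), " levels, ", length(object@x),
      " measurements\n", sep = "")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@kind, "]",
      if (object@converged) "converged" else "NOT converged", "\n")
  est <- signif(object@estimates, 4)
  cat(" ", paste(names(est), est, sep = " = ", collapse = ", "), "\n")
  if (nrow(object@ci)) {
    for (i in seq_len(nrow(object@ci)))
      cat("  ", rownames(object@ci)[i], " 95% CI [",
          signif(object@ci[i, 1], 4), ", ", signif(object@ci[i, 2], 4),
          "]\n", sep = "")
  }
  cat("  RSS", signif(object@rss, 4), "| AICc", signif(object@aicc, 4))
  if (length(object@flags)) cat(" | flags:", paste(object@flags, collapse = ", "))
  cat("\n")
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison: selected =", object@selected, "\n")
  print(object@table)
})
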