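# Shared builders for simulated test fields. Small 25.92 um fields (240 px)
# keep rendering fast while holding enough spots for counting statistics.

quickConfig <- function(seed, fieldSize = 25.92, frames = 5L,
                        photons = 300, ...) {
  simulationConfig(fieldSize = fieldSize, frames = frames,
                   photonsPerFluorophore = photons, seed = seed, ...)
}

# Render a protein field and return image + surface.
renderField <- function(rho, seed, frames = 5L, photons = 300, ...) {
  cfg <- quickConfig(seed, frames = frames, photons = photons, ...)
  surf <- simulateProteinSurface(rho, cfg)
  st <- renderImageStack(list(p = surf), cfg)
  list(cfg = cfg, surf = surf,
       img = averageInitialFrames(st, frames, "p"), stack = st)
}

# Recall/precision of detection against interior ground truth, one-to-one
# matching at 2 px.
detectionScore <- function(rho, seed, photons = 62, frames = 10L) {
  fl <- renderField(rho, seed, frames = frames, photons = photons)
  sl <- detectSpots(fl$img, fl$cfg@pixelSize, fl$cfg@psfSigma)
  sp <- spots(sl)
  marg <- 4 * fl$cfg@pixelSize
  interior <- fl$surf@points[, 1] > marg &
    fl$surf@points[, 1] < fl$cfg@fieldSize - marg &
    fl$surf@points[, 2] > marg &
    fl$surf@points[, 2] < fl$cfg@fieldSize - marg
  tp <- fl$surf@points[interior, , drop = FALSE]
  mr <- matchSpots(data.frame(x = tp[, 1], y = tp[, 2]), sp,
                   matchRadius = 2 * fl$cfg@pixelSize,
                   fieldArea = fl$cfg@fieldSize^2)
  list(matched = mr@nMatched, nTruth = nrow(tp), nDet = nrow(sp),
       pairs = mr@pairs, truth = tp, det = sp)
}

# Measured spot density and total intensity of one field (calibration
# protocol: tighter 2 px non-maximum suppression for low-density ladders).
calMeasure <- function(rho, seed, photons = 300, frames = 5L) {
  fl <- renderField(rho, seed, frames = frames, photons = photons)
  sl <- detectSpots(fl$img, fl$cfg@pixelSize, fl$cfg@psfSigma,
                    minSeparation = 2L)
  c(realized = nrow(fl$surf@points) / fl$cfg@fieldSize^2,
    spotDensity = countSpotDensity(sl),
    intensity = measureTotalIntensity(fl$img, fl$cfg@cameraOffset))
}
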