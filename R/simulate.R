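# Synthetic-data generator: protein point patterns, vesicle docking,
# diffraction-limited rendering with camera noise, photobleaching traces and
# binding time courses. Every operation is a pure function of its arguments
# and the config seed: a per-stage substream is derived from config@seed so
# repeated calls with the same config are bit-identical.

#' Create a simulation configuration
#'
#' Defaults describe a 60x TIRF objective on an sCMOS camera: 0.108 um
#' pixels, 0.13 um PSF sigma, a 102.4 um square field, 10 frames at 100 ms,
#' offset 100 counts and 2 counts read noise.
#'
#' @param fieldSize side of the square field of view (um).
#' @param pixelSize physical pixel size (um/px).
#' @param psfSigma PSF standard deviation (um).
#' @param frames frames per acquisition.
#' @param frameInterval frame interval (s).
#' @param photonsPerFluorophore expected photons per fluorophore per frame.
#' @param readNoiseSd Gaussian read noise sd (counts).
#' @param cameraOffset camera offset (counts).
#' @param crosstalk square mixing matrix (rows: source, cols: destination),
#'   unit diagonal; default no crosstalk for one channel.
#' @param seed integer top-level seed (NA for ambient RNG).
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(fieldSize = 102.4, pixelSize = 0.108,
                             psfSigma = 0.13, frames = 10L,
                             frameInterval = 0.1,
                             photonsPerFluorophore = 1000,
                             readNoiseSd = 2, cameraOffset = 100,
                             crosstalk = diag(1), seed = NA_integer_) {
  new("SimulationConfig", fieldSize = as.numeric(fieldSize),
      pixelSize = as.numeric(pixelSize), psfSigma = as.numeric(psfSigma),
      frames = as.integer(frames), frameInterval = as.numeric(frameInterval),
      photonsPerFluorophore = as.numeric(photonsPerFluorophore),
      readNoiseSd = as.numeric(readNoiseSd),
      cameraOffset = as.numeric(cameraOffset),
      crosstalk = as.matrix(crosstalk), seed = as.integer(seed))
}

#' Simulate a surface-tethered protein field
#'
#' Homogeneous spatial Poisson point process at the requested density over
#' the square field; an optional fraction of points carries multiplicity 2
#' (dimers pulled down as one tethering event).
#'
#' @param density molecules/um^2, >= 0.
#' @param config a [SimulationConfig-class].
#' @param dimerFraction fraction of points with two fluorophores, in [0, 1].
#' @return a [ProteinSurface-class].
#' @export
simulateProteinSurface <- function(density, config, dimerFraction = 0) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(density) != 1L || is.na(density) || density < 0)
    stop("'density' must be a single non-negative number (molecules/um^2)")
  if (dimerFraction < 0 || dimerFraction > 1)
    stop("'dimerFraction' must be in [0, 1]")
  area <- config@fieldSize^2
  withSubSeed(config@seed, "protein-surface", {
    n <- stats::rpois(1L, density * area)
    pts <- cbind(stats::runif(n, 0, config@fieldSize),
                 stats::runif(n, 0, config@fieldSize))
    mult <- ifelse(stats::runif(n) < dimerFraction, 2L, 1L)
    new("ProteinSurface", points = pts, multiplicity = as.integer(mult),
        density = density, fieldSize = config@fieldSize)
  })
}

#' Classify binding sites on a protein field
#'
#' Proteins with no neighbour within the reach `d` are geometrically
#' isolated. The remainder are paired by greedy mutual-nearest-neighbour
#' pairing within `d`; leftovers (odd members of triplets and larger
#' cliques) are treated as monomeric binding sites.
#'
#' @param surface a [ProteinSurface-class].
#' @param d cooperation reach (um).
#' @return list with `pairs` (m x 2 index matrix), `singles` (indices of
#'   monomeric sites, including pairing leftovers), and `isolated` (logical
#'   per protein: no neighbour within d).
#' @export
classifyBindingSites <- function(surface, d) {
  stopifnot(is(surface, "ProteinSurface"))
  if (d <= 0) stop("'d' must be positive")
  pts <- surface@points
  n <- nrow(pts)
  if (n == 0L)
    return(list(pairs = matrix(integer(0), ncol = 2), singles = integer(0),
                isolated = logical(0)))
  nn <- nnWithin(pts, d)
  isolated <- is.na(nn$idx)
  pairs <- mutualNNPairs(pts, d)
  paired <- rep(FALSE, n)
  if (nrow(pairs)) paired[c(pairs)] <- TRUE
  list(pairs = pairs, singles = which(!paired), isolated = isolated)
}

#' Simulate vesicle docking on a protein field
#'
#' Sites are classified with [classifyBindingSites()] (for cooperative
#' models) or taken as one independent site per protein (Langmuir). Each
#' site is occupied independently with probability
#' alpha * V / (V + K_d,site); occupied sites emit one vesicle at the site
#' centroid with a log-normal brightness factor (sdlog 0.3), reproducing a
#' peaked spot-intensity histogram with a bright tail.
#'
#' @param surface a [ProteinSurface-class].
#' @param model a [LangmuirModel-class] or [CooperativeModel-class].
#' @param conc vesicle concentration (pM), >= 0.
#' @param config a [SimulationConfig-class] (supplies the seed).
#' @return a [VesicleField-class].
#' @export
simulateVesicleBinding <- function(surface, model, conc, config) {
  stopifnot(is(surface, "ProteinSurface"), is(config, "SimulationConfig"))
  if (conc < 0) stop("'conc' must be non-negative")
  if (!(is(model, "LangmuirModel") || is(model, "CooperativeModel")))
    stop("unsupported model kind; supported: LangmuirModel, CooperativeModel")
  pts <- surface@points
  if (is(model, "LangmuirModel")) {
    sitePos <- pts
    siteKd <- rep(model@kd, nrow(pts))
    siteClass <- rep("monomeric", nrow(pts))
    alpha <- model@alpha
  } else {
    cls <- classifyBindingSites(surface, model@d)
    pairPos <- if (nrow(cls$pairs))
      (pts[cls$pairs[, 1], , drop = FALSE] + pts[cls$pairs[, 2], , drop = FALSE]) / 2
    else matrix(numeric(0), ncol = 2)
    sitePos <- rbind(pts[cls$singles, , drop = FALSE], pairPos)
    siteKd <- c(rep(model@kd1, length(cls$singles)),
                rep(model@kd2, nrow(cls$pairs)))
    siteClass <- c(rep("monomeric", length(cls$singles)),
                   rep("paired", nrow(cls$pairs)))
    alpha <- model@alpha
  }
  withSubSeed(config@seed, "vesicle-binding", {
    p <- alpha * .occupancy(conc, siteKd)
    occ <- stats::runif(length(p)) < p
    k <- sum(occ)
    new("VesicleField",
        positions = sitePos[occ, , drop = FALSE],
        brightness = stats::rlnorm(k, meanlog = 0, sdlog = 0.3),
        siteClass = siteClass[occ],
        fieldSize = surface@fieldSize)
  })
}

#' @describeIn asEmitters protein surface: photons = multiplicity x
#'   photonsPerFluorophore.
#' @export
setMethod("asEmitters", "ProteinSurface", function(object, config, ...) {
  data.frame(x = object@points[, 1], y = object@points[, 2],
             photons = object@multiplicity * config@photonsPerFluorophore)
})

#' @describeIn asEmitters vesicle field: photons = brightness x
#'   `photonScale` x photonsPerFluorophore (vesicles carry many dye
#'   molecules; default scale 10).
#' @param photonScale vesicle-to-fluorophore photon budget ratio.
#' @export
setMethod("asEmitters", "VesicleField", function(object, config, photonScale = 10, ...) {
  data.frame(x = object@positions[, 1], y = object@positions[, 2],
             photons = object@brightness * photonScale * config@photonsPerFluorophore)
})

#' @describeIn asEmitters data.frame with columns x, y, photons: passed
#'   through.
#' @export
setMethod("asEmitters", "data.frame", function(object, config, ...) {
  stopifnot(all(c("x", "y", "photons") %in% names(object)))
  object
})

# Expected-photon image for a set of emitters (pixel-integrated Gaussian).
.expectedImage <- function(emitters, config) {
  npx <- as.integer(round(config@fieldSize / config@pixelSize))
  img <- matrix(0, nrow = npx, ncol = npx)
  if (!nrow(emitters)) return(img)
  sig <- config@psfSigma / config@pixelSize
  halfw <- as.integer(ceiling(5 * sig)) + 1L
  xpx <- emitters$x / config@pixelSize
  ypx <- emitters$y / config@pixelSize
  for (i in seq_len(nrow(emitters))) {
    cx <- round(xpx[i]); cy <- round(ypx[i])
    xs <- max(0L, cx - halfw):min(npx - 1L, cx + halfw)
    ys <- max(0L, cy - halfw):min(npx - 1L, cy + halfw)
    if (!length(xs) || !length(ys)) next
    fx <- stats::pnorm((xs + 0.5 - xpx[i]) / sig) -
          stats::pnorm((xs - 0.5 - xpx[i]) / sig)
    fy <- stats::pnorm((ys + 0.5 - ypx[i]) / sig) -
          stats::pnorm((ys - 0.5 - ypx[i]) / sig)
    # rows index y, columns index x
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] +
      emitters$photons[i] * outer(fy, fx)
  }
  img
}

#' Render emitters into a noisy multi-frame image stack
#'
#' Each emitter is rendered as an isotropic 2-D Gaussian (sigma = psfSigma)
#' integrated over pixels. Channel mixing by the config crosstalk matrix is
#' applied to the expected photon images before noise. Each frame then
#' receives per-pixel Poisson shot noise (in photons) and additive Gaussian
#' read noise on top of the camera offset; pixel values are floored at 0.
#'
#' @param emitters a named list, one element per channel: a
#'   [ProteinSurface-class], [VesicleField-class], data.frame with columns
#'   x, y, photons, or NULL (empty channel).
#' @param config a [SimulationConfig-class]; `config@crosstalk` must match
#'   the number of channels.
#' @param photonScale vesicle photon-budget scale passed to [asEmitters()].
#' @param noise apply shot and read noise (default TRUE); `noise = FALSE`
#'   returns the expected (noiseless) image plus offset, e.g. for flux
#'   checks.
#' @return an [ImageStack-class] (rows index y, columns x).
#' @export
renderImageStack <- function(emitters, config, photonScale = 10,
                             noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.list(emitters) || is.data.frame(emitters))
    emitters <- list(ch1 = emitters)
  if (is.null(names(emitters)) || any(!nzchar(names(emitters))))
    names(emitters) <- paste0("ch", seq_along(emitters))
  nch <- length(emitters)
  if (nrow(config@crosstalk) != nch)
    stop("crosstalk matrix dimension must equal the number of channels")
  if (config@psfSigma < config@pixelSize / 4)
    warning("undersampled PSF: psfSigma < pixelSize/4")
  expected <- lapply(emitters, function(e) {
    if (is.null(e)) e <- data.frame(x = numeric(0), y = numeric(0), photons = numeric(0))
    df <- asEmitters(e, config, photonScale = photonScale)
    if (nrow(df) && (any(df$x < 0) || any(df$x > config@fieldSize) ||
                     any(df$y < 0) || any(df$y > config@fieldSize)))
      stop("all emitters must lie within the field")
    .expectedImage(df, config)
  })
  # channel mixing before noise: observed_c = sum_src beta[src, c] E_src
  mixed <- vector("list", nch)
  for (c in seq_len(nch)) {
    acc <- expected[[1]] * config@crosstalk[1, c]
    if (nch > 1) for (s in 2:nch) acc <- acc + expected[[s]] * config@crosstalk[s, c]
    mixed[[c]] <- acc
  }
  npx <- nrow(mixed[[1]])
  withSubSeed(config@seed, "render", {
    channels <- lapply(mixed, function(E) {
      arr <- array(0, dim = c(config@frames, npx, npx))
      for (f in seq_len(config@frames)) {
        frame <- if (noise)
          matrix(stats::rpois(length(E), E), nrow = npx) + config@cameraOffset
        else E + config@cameraOffset
        if (noise && config@readNoiseSd > 0)
          frame <- frame + matrix(stats::rnorm(length(E), 0, config@readNoiseSd),
                                  nrow = npx)
        arr[f, , ] <- pmax(frame, 0)
      }
      arr
    })
    names(channels) <- names(emitters)
    new("ImageStack", channels = channels, pixelSize = config@pixelSize,
        frameInterval = config@frameInterval)
  })
}

#' Simulate a stepwise photobleaching trace
#'
#' Each of `nFluorophores` fluorophores bleaches at an independent
#' exponentially distributed time with rate `bleachRate`; the trace is
#' stepSize x (surviving count) + background + Gaussian noise, sampled at
#' the frame interval.
#'
#' @param nFluorophores initial fluorophore count, >= 1.
#' @param stepSize intensity per fluorophore (counts).
#' @param bleachRate bleaching rate (1/s), > 0.
#' @param frames number of frames.
#' @param frameInterval frame interval (s).
#' @param noiseSd Gaussian noise sd (counts).
#' @param background baseline level (counts).
#' @param seed integer seed (NA for ambient RNG).
#' @return numeric vector of intensities, one per frame; the level at frame
#'   f counts fluorophores alive at the frame start (f-1) dt, so the first
#'   frame always shows the full complement.
#' @export
simulateBleachTrace <- function(nFluorophores, stepSize, bleachRate,
                                frames = 300L, frameInterval = 0.1,
                                noiseSd = 0, background = 0,
                                seed = NA_integer_) {
  if (nFluorophores < 1L) stop("'nFluorophores' must be >= 1")
  if (stepSize <= 0) stop("'stepSize' must be positive")
  if (bleachRate <= 0) stop("'bleachRate' must be positive")
  withSubSeed(seed, "bleach-trace", {
    tb <- stats::rexp(nFluorophores, rate = bleachRate)
    # level sampled at the frame start: frame 1 always shows the full
    # complement, as a camera integrating from t = 0 would
    tt <- (seq_len(frames) - 1L) * frameInterval
    surviving <- vapply(tt, function(t) sum(tb > t), 0L)
    stepSize * surviving + background +
      if (noiseSd > 0) stats::rnorm(frames, 0, noiseSd) else 0
  })
}

#' Simulate an equilibrium-approach binding time course
#'
#' N(t) = N_eq (1 - exp(-k_obs t)) with k_obs = k_on V + k_off. When
#' `area` is given, Poisson counting noise is added by drawing bound counts
#' over that area.
#'
#' @param model a [KineticModel-class].
#' @param conc vesicle concentration (pM).
#' @param times non-negative, increasing times (s).
#' @param area optional field area (um^2) for Poisson counting noise.
#' @param seed integer seed (NA for ambient RNG).
#' @return a [BindingCurve-class] with xKind "time".
#' @export
simulateBindingTimecourse <- function(model, conc, times, area = NULL,
                                      seed = NA_integer_) {
  stopifnot(is(model, "KineticModel"))
  if (any(times < 0) || is.unsorted(times, strictly = FALSE))
    stop("'times' must be non-negative and increasing")
  n <- kineticN(times, model, conc)
  if (!is.null(area)) {
    n <- withSubSeed(seed, "timecourse", stats::rpois(length(n), n * area) / area)
  }
  bindingCurve(times, n, "time", conc = conc)
}
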