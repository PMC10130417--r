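#' @import methods
NULL

#' Imaging and simulation configuration
#'
#' Holds the optical and camera parameters shared by the simulator and, where
#' relevant, by the analysis functions. The field is square with side
#' `fieldSize` micrometres; pixel (0,0) has its centre at (0,0) um, x runs
#' rightward and y downward.
#'
#' @slot fieldSize numeric(1), side of the square field of view (um).
#' @slot pixelSize numeric(1), physical pixel size (um/px).
#' @slot psfSigma numeric(1), standard deviation of the isotropic Gaussian
#'   point-spread function (um).
#' @slot frames integer(1), number of frames per acquisition.
#' @slot frameInterval numeric(1), time between frames (s).
#' @slot photonsPerFluorophore numeric(1), expected photon counts collected
#'   per fluorophore per frame.
#' @slot readNoiseSd numeric(1), Gaussian camera read noise (counts).
#' @slot cameraOffset numeric(1), additive camera offset (counts).
#' @slot crosstalk numeric matrix of bleed-through coefficients; rows are
#'   source channels, columns destination channels; unit diagonal,
#'   off-diagonals in [0, 1).
#' @slot seed integer(1) or NA; top-level seed from which all per-stage
#'   random substreams are derived. Identical config (including seed) gives
#'   bit-identical simulator output.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    fieldSize = "numeric", pixelSize = "numeric", psfSigma = "numeric",
    frames = "integer", frameInterval = "numeric",
    photonsPerFluorophore = "numeric", readNoiseSd = "numeric",
    cameraOffset = "numeric", crosstalk = "matrix", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  for (s in c("fieldSize", "pixelSize", "psfSigma", "frameInterval"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  if (object@frames < 1L) msg <- c(msg, "'frames' must be >= 1")
  if (object@photonsPerFluorophore < 0) msg <- c(msg, "'photonsPerFluorophore' must be >= 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "'readNoiseSd' must be >= 0")
  ct <- object@crosstalk
  if (nrow(ct) != ncol(ct)) msg <- c(msg, "crosstalk matrix must be square")
  else {
    if (any(abs(diag(ct) - 1) > 1e-12)) msg <- c(msg, "crosstalk matrix must have unit diagonal")
    off <- ct[row(ct) != col(ct)]
    if (length(off) && (any(off < 0) || any(off >= 1)))
      msg <- c(msg, "off-diagonal crosstalk must be in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Surface-tethered protein point pattern
#'
#' A realization of fluorescently tagged protein molecules on the imaging
#' surface. Positions are in micrometres; `multiplicity` gives the number of
#' fluorophores per point (>= 1, e.g. 2 for a dimer).
#'
#' @slot points numeric matrix (n x 2) of (x, y) positions in um.
#' @slot multiplicity integer vector, fluorophores per point.
#' @slot density numeric(1), nominal generating density (molecules/um^2).
#' @slot fieldSize numeric(1), side of the square field (um).
#'
#' @exportClass ProteinSurface
setClass("ProteinSurface",
  representation(points = "matrix", multiplicity = "integer",
                 density = "numeric", fieldSize = "numeric")
)

setValidity("ProteinSurface", function(object) {
  msg <- character(0)
  if (ncol(object@points) != 2L) msg <- c(msg, "'points' must have two columns (x, y)")
  if (nrow(object@points) != length(object@multiplicity))
    msg <- c(msg, "one multiplicity per point required")
  if (length(object@multiplicity) && any(object@multiplicity < 1L))
    msg <- c(msg, "multiplicity must be >= 1")
  if (nrow(object@points) &&
      (any(object@points < 0) || any(object@points > object@fieldSize)))
    msg <- c(msg, "all points must lie within the field bounds")
  if (object@density < 0) msg <- c(msg, "'density' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Bound-vesicle field
#'
#' Vesicles captured by binding sites on a [ProteinSurface-class]. Each bound
#' vesicle carries a unitless label-brightness factor and the class of the
#' site that captured it ("monomeric" or "paired").
#'
#' @slot positions numeric matrix (n x 2), vesicle positions (um).
#' @slot brightness numeric vector, per-vesicle brightness factors.
#' @slot siteClass character vector, "monomeric" or "paired".
#' @slot fieldSize numeric(1), side of the square field (um).
#'
#' @exportClass VesicleField
setClass("VesicleField",
  representation(positions = "matrix", brightness = "numeric",
                 siteClass = "character", fieldSize = "numeric")
)

setValidity("VesicleField", function(object) {
  msg <- character(0)
  n <- nrow(object@positions)
  if (ncol(object@positions) != 2L) msg <- c(msg, "'positions' must have two columns")
  if (length(object@brightness) != n || length(object@siteClass) != n)
    msg <- c(msg, "brightness and siteClass must match the number of vesicles")
  if (n && !all(object@siteClass %in% c("monomeric", "paired")))
    msg <- c(msg, "siteClass must be 'monomeric' or 'paired'")
  if (length(object@brightness) && any(object@brightness <= 0))
    msg <- c(msg, "brightness factors must be positive")
  if (length(msg)) msg else TRUE
})

#' Multi-frame, multi-channel image stack
#'
#' @slot channels named list of 3-D numeric arrays, each frames x rows x cols
#'   (counts). All channels share the same dimensions.
#' @slot pixelSize numeric(1), um/px.
#' @slot frameInterval numeric(1), s.
#'
#' @exportClass ImageStack
setClass("ImageStack",
  representation(channels = "list", pixelSize = "numeric",
                 frameInterval = "numeric")
)

setValidity("ImageStack", function(object) {
  msg <- character(0)
  if (!length(object@channels)) msg <- c(msg, "at least one channel required")
  dims <- lapply(object@channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "each channel must be a frames x rows x cols array")
  else {
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1L)
      msg <- c(msg, "all channels must share dimensions")
    if (dims[[1]][1] < 1L) msg <- c(msg, "at least one frame required")
  }
  if (is.null(names(object@channels)) || anyDuplicated(names(object@channels)))
    msg <- c(msg, "channels must be uniquely named")
  if (length(msg)) msg else TRUE
})

#' Detected diffraction-limited spots
#'
#' Spot positions are continuous micrometre coordinates with the centre of
#' pixel (0,0) at (0,0) um. `integrated` is the background-subtracted
#' integrated intensity (amplitude x 2 pi sigma^2 in pixel units, counts).
#'
#' @slot spots data.frame with columns channel, x, y (um), amplitude,
#'   integrated, sigma (um).
#' @slot metadata list of detection settings (threshold, background, noise
#'   sd, frames averaged, minimum separation).
#'
#' @exportClass SpotList
setClass("SpotList",
  representation(spots = "data.frame", metadata = "list")
)

setValidity("SpotList", function(object) {
  need <- c("channel", "x", "y", "amplitude", "integrated", "sigma")
  if (!all(need %in% names(object@spots)))
    return(paste("spots data.frame must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@spots) && any(object@spots$integrated <= 0))
    return("integrated intensities must be positive")
  TRUE
})

#' Intensity-to-density calibration
#'
#' A linear calibration I = a * rho + b between total field intensity and
#' molecular surface density, built in the optically resolvable low-density
#' regime (rho <= ~1 spot/um^2) and extrapolated beyond it.
#'
#' @slot slope numeric(1), counts per (spot/um^2).
#' @slot intercept numeric(1), counts (background).
#' @slot range numeric(2), density range used for the fit (spots/um^2).
#' @slot diagnostics list: r.squared, residual sd, number of levels, weights
#'   used.
#'
#' @exportClass DensityCalibration
setClass("DensityCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 range = "numeric", diagnostics = "list")
)

setValidity("DensityCalibration", function(object) {
  if (object@slope <= 0) return("calibration slope must be positive")
  TRUE
})

#' Photobleaching step analysis of a single-spot trace
#'
#' @slot nSteps integer(1), number of downward bleaching steps.
#' @slot stepSize numeric(1), median downward level change (counts).
#' @slot initialLevel numeric(1), first fitted level minus final level.
#' @slot changepoints integer vector, frame indices of level changes
#'   (strictly increasing; a changepoint at k means a new level from frame
#'   k + 1).
#' @slot levels numeric vector, fitted piecewise-constant levels.
#' @slot residualSd numeric(1), residual standard deviation.
#' @slot flags character vector, e.g. "non-bleaching".
#'
#' @exportClass BleachAnalysis
setClass("BleachAnalysis",
  representation(nSteps = "integer", stepSize = "numeric",
                 initialLevel = "numeric", changepoints = "integer",
                 levels = "numeric", residualSd = "numeric",
                 flags = "character")
)

setValidity("BleachAnalysis", function(object) {
  msg <- character(0)
  if (object@nSteps < 0L) msg <- c(msg, "nSteps must be >= 0")
  if (length(object@changepoints) > 1L && any(diff(object@changepoints) <= 0L))
    msg <- c(msg, "changepoints must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Two-channel colocalization result
#'
#' @slot nA,nB integer(1), spot counts per channel.
#' @slot nMatched integer(1), one-to-one matched pairs within the radius.
#' @slot fractionA,fractionB numeric(1), colocalized fraction per channel.
#' @slot chanceFraction numeric(1), chance-expected colocalized fraction
#'   1 - exp(-rho_B * pi * r^2) (reported, not subtracted).
#' @slot matchRadius numeric(1), um.
#' @slot pairs data.frame with columns idxA, idxB, distance (um).
#'
#' @exportClass ColocalizationResult
setClass("ColocalizationResult",
  representation(nA = "integer", nB = "integer", nMatched = "integer",
                 fractionA = "numeric", fractionB = "numeric",
                 chanceFraction = "numeric", matchRadius = "numeric",
                 pairs = "data.frame")
)

setValidity("ColocalizationResult", function(object) {
  msg <- character(0)
  if (object@nMatched > min(object@nA, object@nB))
    msg <- c(msg, "nMatched cannot exceed either channel count")
  fr <- c(object@fractionA, object@fractionB)
  fr <- fr[is.finite(fr)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    msg <- c(msg, "fractions must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---- binding models -------------------------------------------------------

#' Virtual parent of all adsorption/binding models
#' @exportClass BindingModel
setClass("BindingModel", representation("VIRTUAL"))

#' Simple Langmuir adsorption
#'
#' Every surface protein is an independent binding site with equilibrium
#' constant `kd`; bound-vesicle density is
#' N_b = alpha * rho * V / (V + K_d) with vesicle concentration V and K_d in
#' common molar units (nM internally).
#'
#' @slot kd numeric(1), equilibrium constant (nM).
#' @slot alpha numeric(1), capture-efficiency scale in (0, 1].
#' @exportClass LangmuirModel
setClass("LangmuirModel", contains = "BindingModel",
  representation(kd = "numeric", alpha = "numeric")
)
setValidity("LangmuirModel", function(object) {
  if (object@kd <= 0) return("kd must be positive")
  if (object@alpha <= 0 || object@alpha > 1) return("alpha must be in (0, 1]")
  TRUE
})

#' Density-dependent cooperation model
#'
#' Proteins whose nearest neighbour lies within the geometric reach `d` form
#' paired sites with their own (typically much smaller) equilibrium constant
#' `kd2`; isolated proteins bind with `kd1`. Site densities follow the
#' spatial-Poisson nearest-neighbour law (see [siteDensities()]).
#'
#' @slot kd1 numeric(1), single-protein site constant (nM).
#' @slot kd2 numeric(1), paired-site constant (nM).
#' @slot d numeric(1), cooperation reach (um).
#' @slot alpha numeric(1), capture-efficiency scale in (0, 1].
#' @exportClass CooperativeModel
setClass("CooperativeModel", contains = "BindingModel",
  representation(kd1 = "numeric", kd2 = "numeric", d = "numeric",
                 alpha = "numeric")
)
setValidity("CooperativeModel", function(object) {
  if (any(c(object@kd1, object@kd2, object@d) <= 0))
    return("kd1, kd2 and d must be positive")
  if (object@alpha <= 0 || object@alpha > 1) return("alpha must be in (0, 1]")
  TRUE
})

#' Hill model of vesicle-concentration dependence
#'
#' N = N_max * V^n / (V^n + K_half^n). `khalf` is in the same concentration
#' units as the curve it is fitted to (typically particles/ml).
#'
#' @slot nmax numeric(1), saturation density (vesicles/um^2).
#' @slot khalf numeric(1), half-saturation concentration.
#' @slot n numeric(1), Hill coefficient.
#' @exportClass HillModel
setClass("HillModel", contains = "BindingModel",
  representation(nmax = "numeric", khalf = "numeric", n = "numeric")
)
setValidity("HillModel", function(object) {
  if (any(c(object@nmax, object@khalf, object@n) <= 0))
    return("nmax, khalf and n must be positive")
  TRUE
})

#' Sigmoidal dose-inhibition model
#'
#' N = N_bg + (N_0 - N_bg) / (1 + (dose/IC50)^h).
#'
#' @slot n0 numeric(1), uninhibited level (vesicles/um^2).
#' @slot nbg numeric(1), residual floor (vesicles/um^2).
#' @slot ic50 numeric(1), half-maximal inhibitory dose (uM).
#' @slot h numeric(1), slope factor.
#' @exportClass InhibitionModel
setClass("InhibitionModel", contains = "BindingModel",
  representation(n0 = "numeric", nbg = "numeric", ic50 = "numeric",
                 h = "numeric")
)
setValidity("InhibitionModel", function(object) {
  msg <- character(0)
  if (object@nbg < 0) msg <- c(msg, "nbg must be >= 0")
  if (object@n0 <= object@nbg) msg <- c(msg, "n0 must exceed nbg")
  if (object@ic50 <= 0 || object@h <= 0) msg <- c(msg, "ic50 and h must be positive")
  if (length(msg)) msg else TRUE
})

#' Pseudo-first-order binding kinetics
#'
#' N(t) = N_eq * (1 - exp(-(k_on V + k_off) t)).
#'
#' @slot kon numeric(1), association rate (1/(pM s)).
#' @slot koff numeric(1), dissociation rate (1/s).
#' @slot neq numeric(1), equilibrium bound density (vesicles/um^2).
#' @exportClass KineticModel
setClass("KineticModel", contains = "BindingModel",
  representation(kon = "numeric", koff = "numeric", neq = "numeric")
)
setValidity("KineticModel", function(object) {
  if (object@kon < 0 || object@koff < 0) return("kon and koff must be >= 0")
  if (object@neq < 0) return("neq must be >= 0")
  TRUE
})

#' Replicated binding measurements
#'
#' Long-format measurements of bound-vesicle surface density against one of:
#' protein surface density ("density", molecules/um^2), vesicle concentration
#' ("concentration", caller's units, typically particles/ml), inhibitor dose
#' ("dose", uM), or time ("time", s). Replicates share identical x values.
#'
#' @slot x numeric vector of the independent variable (>= 0).
#' @slot y numeric vector of bound-vesicle densities (vesicles/um^2, >= 0).
#' @slot xKind character(1), one of "density", "concentration", "dose",
#'   "time".
#' @slot conc numeric(1), vesicle concentration (pM) at which a density-axis
#'   curve was measured; NA otherwise.
#'
#' @exportClass BindingCurve
setClass("BindingCurve",
  representation(x = "numeric", y = "numeric", xKind = "character",
                 conc = "numeric")
)
setValidity("BindingCurve", function(object) {
  msg <- character(0)
  if (length(object@x) != length(object@y)) msg <- c(msg, "x and y must have equal length")
  if (any(object@x < 0)) msg <- c(msg, "x must be non-negative")
  if (any(object@y < 0)) msg <- c(msg, "y must be non-negative")
  if (!object@xKind %in% c("density", "concentration", "dose", "time"))
    msg <- c(msg, "xKind must be one of density/concentration/dose/time")
  if (length(msg)) msg else TRUE
})

#' Nonlinear fit result
#'
#' @slot model fitted [BindingModel-class] object.
#' @slot kind character(1) model kind.
#' @slot estimates named numeric, point estimates on the natural scale.
#' @slot ci numeric matrix (parameters x 2) of 95% bootstrap limits, or
#'   0-row matrix when no bootstrap was run.
#' @slot rss numeric(1), weighted residual sum of squares at the optimum.
#' @slot aicc numeric(1).
#' @slot converged logical(1).
#' @slot flags character vector ("at-bound", "non-inhibitory", ...).
#' @slot nObs integer(1), number of distinct x levels used.
#' @slot seed integer(1), seed governing starts and bootstrap.
#' @slot details list (per-start RSS, bootstrap draws, weights).
#'
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "BindingModel", kind = "character",
                 estimates = "numeric", ci = "matrix", rss = "numeric",
                 aicc = "numeric", converged = "logical",
                 flags = "character", nObs = "integer", seed = "integer",
                 details = "list")
)

#' Model comparison by AICc
#'
#' @slot table data.frame with one row per candidate: kind, nPar, rss, aicc,
#'   dAicc, converged.
#' @slot selected character(1), selected model kind (or NA if incomplete).
#' @slot rule character(1), decision rule record.
#' @exportClass ModelComparison
setClass("ModelComparison",
  representation(table = "data.frame", selected = "character",
                 rule = "character")
)
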