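#' Predicted bound-vesicle density under a binding model
#'
#' Evaluates the closed-form equilibrium (or kinetic) prediction of a
#' [BindingModel-class] along the axis appropriate to the model:
#' protein density for Langmuir/cooperative models (with the vesicle
#' concentration passed as `conc`, pM), concentration for Hill models, dose
#' for inhibition models, and time for kinetic models (with `conc` in pM).
#'
#' @param model a [BindingModel-class] object.
#' @param x numeric vector of the independent variable.
#' @param ... further arguments (`conc` for density/time axes).
#' @return numeric vector of bound-vesicle densities (vesicles/um^2).
#' @seealso [langmuirNb()], [cooperativeNb()], [hillN()], [inhibitionN()],
#'   [kineticN()]
#' @export
setGeneric("predictNb", function(model, x, ...) standardGeneric("predictNb"))

#' Spot table of a SpotList
#' @param object a [SpotList-class].
#' @return data.frame of detected spots.
#' @export
setGeneric("spots", function(object) standardGeneric("spots"))

#' Number of detected spots
#' @param object a [SpotList-class].
#' @export
setGeneric("nSpots", function(object) standardGeneric("nSpots"))

#' Calibration slope (counts per spot/um^2)
#' @param object a [DensityCalibration-class].
#' @export
setGeneric("calSlope", function(object) standardGeneric("calSlope"))

#' Calibration intercept (counts)
#' @param object a [DensityCalibration-class].
#' @export
setGeneric("calIntercept", function(object) standardGeneric("calIntercept"))

#' Number of photobleaching steps
#' @param object a [BleachAnalysis-class].
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))

#' Pixel data of one channel
#' @param object an [ImageStack-class].
#' @param channel channel name or index (default first).
#' @export
setGeneric("channelData", function(object, channel = 1L) standardGeneric("channelData"))

#' Channel names of an image stack
#' @param object an [ImageStack-class].
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Coerce a simulated object to renderable emitters
#'
#' Internal-facing generic mapping a [ProteinSurface-class] or
#' [VesicleField-class] to a data.frame of point emitters (x, y in um and
#' expected photons per frame).
#'
#' @param object object to coerce.
#' @param config a [SimulationConfig-class].
#' @param ... further arguments (e.g. `photonScale` for vesicles).
#' @export
setGeneric("asEmitters", function(object, config, ...) standardGeneric("asEmitters"))
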