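# Closed-form adsorption and binding models.
#
# All equilibrium expressions work in molar units internally: vesicle
# concentrations are pM, equilibrium constants are nM, and pM/nM are
# reconciled inside the occupancy terms. Concentrations given as
# particles/ml are converted with particlesPerMlToPM().

#' Construct a simple Langmuir adsorption model
#'
#' @param kd equilibrium constant (nM), > 0.
#' @param alpha capture-efficiency scale in (0, 1].
#' @return a [LangmuirModel-class] object.
#' @examples
#' m <- langmuirModel(kd = 0.25)
#' langmuirNb(rho = 10, conc = 3, m)
#' @export
langmuirModel <- function(kd, alpha = 1) {
  new("LangmuirModel", kd = as.numeric(kd), alpha = as.numeric(alpha))
}

#' Construct a density-dependent cooperation model
#'
#' Two site classes on a spatial-Poisson protein field: isolated proteins
#' bind vesicles with constant `kd1`; proteins whose nearest neighbour lies
#' within the reach `d` act as paired sites with constant `kd2`
#' (typically kd2 << kd1, producing super-linear density dependence).
#'
#' @param kd1 single-protein site constant (nM).
#' @param kd2 paired-site constant (nM).
#' @param d cooperation reach (um); default 0.1 um, the contact footprint of
#'   a ~140 nm vesicle.
#' @param alpha capture-efficiency scale in (0, 1].
#' @return a [CooperativeModel-class] object.
#' @export
cooperativeModel <- function(kd1, kd2, d = 0.1, alpha = 1) {
  new("CooperativeModel", kd1 = as.numeric(kd1), kd2 = as.numeric(kd2),
      d = as.numeric(d), alpha = as.numeric(alpha))
}

#' Construct a Hill model
#' @param nmax saturation bound density (vesicles/um^2).
#' @param khalf half-saturation concentration (units of the curve axis).
#' @param n Hill coefficient.
#' @return a [HillModel-class] object.
#' @export
hillModel <- function(nmax, khalf, n) {
  new("HillModel", nmax = as.numeric(nmax), khalf = as.numeric(khalf),
      n = as.numeric(n))
}

#' Construct a sigmoidal inhibition model
#' @param n0 uninhibited bound density (vesicles/um^2).
#' @param nbg residual floor (vesicles/um^2).
#' @param ic50 half-maximal inhibitory dose (uM).
#' @param h slope factor.
#' @return an [InhibitionModel-class] object.
#' @export
inhibitionModel <- function(n0, nbg = 0, ic50, h = 1) {
  new("InhibitionModel", n0 = as.numeric(n0), nbg = as.numeric(nbg),
      ic50 = as.numeric(ic50), h = as.numeric(h))
}

#' Construct a pseudo-first-order kinetic model
#' @param kon association rate (1/(pM s)).
#' @param koff dissociation rate (1/s).
#' @param neq equilibrium bound density (vesicles/um^2).
#' @return a [KineticModel-class] object.
#' @export
kineticModel <- function(kon, koff, neq) {
  new("KineticModel", kon = as.numeric(kon), koff = as.numeric(koff),
      neq = as.numeric(neq))
}

# occupancy V/(V + Kd), V in pM and Kd in nM
.occupancy <- function(concPM, kdNM) {
  v <- concPM * 1e-3  # nM
  ifelse(v + kdNM == 0, 0, v / (v + kdNM))
}

#' Langmuir bound-vesicle density
#'
#' N_b = alpha * rho * V / (V + K_d).
#'
#' @param rho protein surface density (molecules/um^2), >= 0.
#' @param conc vesicle concentration (pM), >= 0.
#' @param params a [LangmuirModel-class].
#' @return bound-vesicle density (vesicles/um^2).
#' @export
langmuirNb <- function(rho, conc, params) {
  stopifnot(is(params, "LangmuirModel"))
  if (any(rho < 0)) stop("'rho' must be non-negative")
  if (any(conc < 0)) stop("'conc' must be non-negative")
  params@alpha * rho * .occupancy(conc, params@kd)
}

#' Site densities on a spatial-Poisson protein field
#'
#' With lambda = rho * pi * d^2 (the expected number of neighbours within the
#' reach d), the density of isolated-protein sites is s1 = rho * exp(-lambda)
#' and of paired sites s2 = rho * (1 - exp(-lambda)) / 2. The identity
#' s1 + 2 s2 = rho holds exactly: every protein belongs to exactly one site.
#'
#' @param rho protein density (molecules/um^2), >= 0.
#' @param d cooperation reach (um), > 0.
#' @return a list with components `s1` and `s2` (sites/um^2).
#' @examples
#' s <- siteDensities(rho = 2, d = 0.1)
#' s$s1 + 2 * s$s2  # == 2
#' @export
siteDensities <- function(rho, d) {
  if (any(rho < 0)) stop("'rho' must be non-negative")
  if (any(d <= 0)) stop("'d' must be positive")
  lambda <- rho * pi * d^2
  list(s1 = rho * exp(-lambda), s2 = rho * (1 - exp(-lambda)) / 2)
}

#' Cooperative bound-vesicle density
#'
#' N_b = alpha * [ s1 * V/(V + K_d1) + s2 * V/(V + K_d2) ] with site
#' densities from [siteDensities()].
#'
#' @inheritParams langmuirNb
#' @param params a [CooperativeModel-class].
#' @return bound-vesicle density (vesicles/um^2).
#' @export
cooperativeNb <- function(rho, conc, params) {
  stopifnot(is(params, "CooperativeModel"))
  if (any(rho < 0)) stop("'rho' must be non-negative")
  if (any(conc < 0)) stop("'conc' must be non-negative")
  s <- siteDensities(rho, params@d)
  params@alpha * (s$s1 * .occupancy(conc, params@kd1) +
                  s$s2 * .occupancy(conc, params@kd2))
}

#' Hill bound-vesicle density
#'
#' N = N_max * V^n / (V^n + K_half^n); `conc` must be in the units of
#' `params@khalf`.
#'
#' @param conc vesicle concentration (units of khalf), >= 0.
#' @param params a [HillModel-class].
#' @export
hillN <- function(conc, params) {
  stopifnot(is(params, "HillModel"))
  if (any(conc < 0)) stop("'conc' must be non-negative")
  vn <- (conc / params@khalf)^params@n
  params@nmax * vn / (1 + vn)
}

#' Sigmoidal inhibition curve
#'
#' N = N_bg + (N_0 - N_bg) / (1 + (dose/IC50)^h).
#'
#' @param dose inhibitor dose (uM), >= 0.
#' @param params an [InhibitionModel-class].
#' @export
inhibitionN <- function(dose, params) {
  stopifnot(is(params, "InhibitionModel"))
  if (any(dose < 0)) stop("'dose' must be non-negative")
  params@nbg + (params@n0 - params@nbg) / (1 + (dose / params@ic50)^params@h)
}

#' Pseudo-first-order binding time course
#'
#' N(t) = N_eq * (1 - exp(-(k_on V + k_off) t)).
#'
#' @param t time (s), >= 0.
#' @param params a [KineticModel-class].
#' @param conc vesicle concentration (pM).
#' @export
kineticN <- function(t, params, conc) {
  stopifnot(is(params, "KineticModel"))
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(conc < 0)) stop("'conc' must be non-negative")
  kobs <- params@kon * conc + params@koff
  params@neq * (1 - exp(-kobs * t))
}

#' Convert a particle concentration to picomolar
#'
#' c particles/ml corresponds to c * 1000 / N_A mol/l; expressed in pM this
#' is c * 1000 / N_A * 1e12. For example 2e9 particles/ml is ~3 pM.
#'
#' @param c particle concentration (particles/ml), >= 0.
#' @return molar concentration in pM.
#' @examples
#' particlesPerMlToPM(2e9)  # ~3.3 pM
#' @export
particlesPerMlToPM <- function(c) {
  if (any(c < 0)) stop("'c' must be non-negative")
  avogadro <- 6.02214076e23
  c * 1e3 / avogadro * 1e12
}

#' @describeIn predictNb Langmuir: `x` is protein density, `conc` (pM)
#'   required.
#' @param conc vesicle concentration (pM) for density/time-axis models.
#' @export
setMethod("predictNb", "LangmuirModel", function(model, x, conc, ...) {
  langmuirNb(x, conc, model)
})

#' @describeIn predictNb cooperative: `x` is protein density, `conc` (pM)
#'   required.
#' @export
setMethod("predictNb", "CooperativeModel", function(model, x, conc, ...) {
  cooperativeNb(x, conc, model)
})

#' @describeIn predictNb Hill: `x` is vesicle concentration in khalf units.
#' @export
setMethod("predictNb", "HillModel", function(model, x, ...) hillN(x, model))

#' @describeIn predictNb inhibition: `x` is inhibitor dose (uM).
#' @export
setMethod("predictNb", "InhibitionModel", function(model, x, ...) {
  inhibitionN(x, model)
})

#' @describeIn predictNb kinetic: `x` is time (s), `conc` (pM) required.
#' @export
setMethod("predictNb", "KineticModel", function(model, x, conc, ...) {
  kineticN(x, model, conc)
})

#' Construct a binding curve
#'
#' @param x independent variable (see [BindingCurve-class] for kinds).
#' @param y bound-vesicle density (vesicles/um^2).
#' @param xKind one of "density", "concentration", "dose", "time".
#' @param conc vesicle concentration (pM) for density-axis curves.
#' @return a [BindingCurve-class] object.
#' @export
bindingCurve <- function(x, y, xKind = c("density", "concentration", "dose", "time"),
                         conc = NA_real_) {
  xKind <- match.arg(xKind)
  new("BindingCurve", x = as.numeric(x), y = as.numeric(y), xKind = xKind,
      conc = as.numeric(conc))
}

#' Replicate-level summary of a binding curve
#'
#' @param curve a [BindingCurve-class].
#' @return data.frame with columns x, mean, sd, n, one row per distinct x.
#' @export
curveSummary <- function(curve) {
  stopifnot(is(curve, "BindingCurve"))
  xs <- sort(unique(curve@x))
  out <- data.frame(
    x = xs,
    mean = vapply(xs, function(v) mean(curve@y[curve@x == v]), 0),
    sd = vapply(xs, function(v) stats::sd(curve@y[curve@x == v]), 0),
    n = vapply(xs, function(v) sum(curve@x == v), 0L)
  )
  out
}

#' Maximum local log-log slope of a model curve
#'
#' Numerically differentiates log N_b with respect to log rho on a dense
#' grid; used to test for super-linear density dependence (slope > 1 means
#' faster-than-linear growth).
#'
#' @param model a Langmuir or cooperative [BindingModel-class].
#' @param conc vesicle concentration (pM).
#' @param rhoRange numeric(2), density range to scan (molecules/um^2).
#' @param nGrid grid size.
#' @return maximum slope d log N / d log rho over the range.
#' @export
maxLogLogSlope <- function(model, conc, rhoRange = c(0.5, 40), nGrid = 400L) {
  rho <- logSeq(rhoRange[1], rhoRange[2], nGrid)
  nb <- predictNb(model, rho, conc = conc)
  if (any(nb <= 0)) return(NA_real_)
  max(diff(log(nb)) / diff(log(rho)))
}
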