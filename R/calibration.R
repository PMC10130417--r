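# Intensity-to-density calibration in the resolvable low-density regime.

#' Build a linear intensity-to-density calibration
#'
#' Fits total field intensity against measured spot density by weighted
#' least squares using only levels at or below `maxDensity` (default
#' 1 spot/um^2, the single-spot countability ceiling at the diffraction
#' limit). Weights are inverse replicate variances of the intensity; the fit
#' falls back to unweighted least squares when replicates are missing. The
#' intercept is fitted, not forced through the origin, to absorb camera
#' offset and autofluorescence.
#'
#' @param density spot densities (spots/um^2), replicates repeated.
#' @param intensity matching total intensities (counts).
#' @param maxDensity calibration cut-off (spots/um^2).
#' @return a [DensityCalibration-class].
#' @export
buildCalibration <- function(density, intensity, maxDensity = 1.0) {
  if (length(density) != length(intensity))
    stop("'density' and 'intensity' must have equal length")
  ok <- density <= maxDensity
  density <- density[ok]; intensity <- intensity[ok]
  lev <- sort(unique(density))
  if (length(lev) < 3L)
    stop(sprintf("calibration needs >= 3 density levels at rho <= %g; got %d",
                 maxDensity, length(lev)))
  mI <- vapply(lev, function(v) mean(intensity[density == v]), 0)
  vI <- vapply(lev, function(v) stats::var(intensity[density == v]), 0)
  nR <- vapply(lev, function(v) sum(density == v), 0L)
  weighted <- all(is.finite(vI)) && all(vI > 0) && all(nR >= 2L)
  w <- if (weighted) 1 / vI else rep(1, length(lev))
  fit <- stats::lm(mI ~ lev, weights = w)
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  if (!is.finite(a)) stop("rank-deficient calibration: density levels are not distinct")
  if (a <= 0) stop("non-physical calibration: fitted slope is not positive")
  new("DensityCalibration", slope = a, intercept = b, range = range(lev),
      diagnostics = list(r.squared = suppressWarnings(summary(fit)$r.squared),
                         residualSd = stats::sd(stats::residuals(fit)),
                         nLevels = length(lev), weighted = weighted))
}

#' Convert total intensity to molecular surface density
#'
#' rho = (I - b) / a. Extrapolation beyond the calibration range is
#' permitted and flagged in the `extrapolated` attribute; intensities below
#' the intercept return 0 with a warning.
#'
#' @param cal a [DensityCalibration-class].
#' @param intensity total field intensity (counts), vectorized.
#' @return densities (molecules/um^2) with a logical attribute
#'   `extrapolated` marking values beyond the calibration range.
#' @export
intensityToDensity <- function(cal, intensity) {
  stopifnot(is(cal, "DensityCalibration"))
  rho <- (intensity - cal@intercept) / cal@slope
  below <- rho < 0
  if (any(below)) {
    warning("intensity below calibration background; returning 0")
    rho[below] <- 0
  }
  attr(rho, "extrapolated") <- rho > cal@range[2]
  rho
}

#' Linearity / self-quenching diagnostic
#'
#' Fits I = b + a rho + c rho^2 over the full density range and flags the
#' data as nonlinear when the curvature is both statistically significant
#' (|c| > 2 standard errors) and physically meaningful (it reduces the
#' intensity at the highest density by more than 10% of the linear part);
#' negative curvature of this size is the signature of self-quenching.
#'
#' @param density densities spanning the full range (>= 5 levels).
#' @param intensity matching total intensities.
#' @return list with `c` (curvature), `se` (its standard error),
#'   `relativeLoss` (fractional intensity reduction at the maximum
#'   density), and `nonlinear` (logical flag).
#' @export
checkLinearity <- function(density, intensity) {
  if (length(unique(density)) < 5L)
    stop("linearity check needs >= 5 density levels")
  lev <- sort(unique(density))
  mI <- vapply(lev, function(v) mean(intensity[density == v]), 0)
  fit <- stats::lm(mI ~ lev + I(lev^2))
  co <- suppressWarnings(summary(fit))$coefficients
  cc <- co["I(lev^2)", "Estimate"]
  se <- co["I(lev^2)", "Std. Error"]
  a <- co["lev", "Estimate"]
  rmax <- max(lev)
  loss <- if (cc < 0 && a > 0) -cc * rmax^2 / (a * rmax) else 0
  list(c = cc, se = se, relativeLoss = loss,
       nonlinear = is.finite(se) && abs(cc) > 2 * se && loss > 0.10)
}
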