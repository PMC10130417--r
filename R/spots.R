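# Spot detection and counting in averaged TIRF frames.

#' Average the initial frames of an image stack
#'
#' Pixelwise mean of the first `nFrames` frames of one channel; averaging
#' the initial frames suppresses camera noise before spot counting while
#' avoiding the photobleached tail of the movie.
#'
#' @param stack an [ImageStack-class].
#' @param nFrames number of leading frames to average (default 10).
#' @param channel channel name or index.
#' @return numeric matrix (rows index y, columns x).
#' @export
averageInitialFrames <- function(stack, nFrames = 10L, channel = 1L) {
  stopifnot(is(stack, "ImageStack"))
  arr <- channelData(stack, channel)
  avail <- dim(arr)[1]
  if (avail < nFrames)
    stop(sprintf("stack has only %d frame(s); %d requested", avail, nFrames))
  if (nFrames == 1L) return(arr[1L, , ])
  apply(arr[seq_len(nFrames), , , drop = FALSE], c(2, 3), mean)
}

# Least-squares 2-D Gaussian refinement in a (2w+1)^2 window.
# Returns NULL when the fit diverges.
.fitGaussianSpot <- function(img, row0, col0, sigPx, w = 3L) {
  row0 <- unname(row0); col0 <- unname(col0)
  nr <- nrow(img); nc <- ncol(img)
  rows <- (row0 - w):(row0 + w)
  cols <- (col0 - w):(col0 + w)
  if (min(rows) < 1L || max(rows) > nr || min(cols) < 1L || max(cols) > nc)
    return(NULL)
  z <- img[rows, cols]
  ry <- as.numeric(rows); cx <- as.numeric(cols)
  b0 <- min(z)
  a0 <- z[w + 1L, w + 1L] - b0
  if (a0 <= 0) return(NULL)
  start <- c(A = a0, x0 = col0, y0 = row0, logSig = log(sigPx), b = b0)
  resid <- function(p) {
    s <- exp(p[4])
    g <- outer(exp(-(ry - p[3])^2 / (2 * s^2)),
               exp(-(cx - p[2])^2 / (2 * s^2)))
    as.vector(p[1] * g + p[5] - z)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 150)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  sig <- exp(p[["logSig"]])
  if (!is.finite(sig) || p[["A"]] <= 0) return(NULL)
  if (abs(p[["x0"]] - col0) > 2 || abs(p[["y0"]] - row0) > 2) return(NULL)
  if (sig < 0.5 * sigPx || sig > 3 * sigPx) return(NULL)
  list(A = p[["A"]], colPx = p[["x0"]], rowPx = p[["y0"]], sigmaPx = sig,
       b = p[["b"]])
}

#' Detect diffraction-limited spots in a 2-D image
#'
#' Candidates are local maxima within a (2 minSeparation + 1)^2
#' neighbourhood whose background-subtracted peak exceeds the threshold;
#' the background is the image median and the noise scale its MAD. Each
#' candidate is refined by a least-squares 2-D Gaussian fit in a 7x7 px
#' window; fits whose centre moves more than 2 px or whose sigma falls
#' outside [0.5, 3] x the nominal PSF sigma are discarded. The integrated
#' intensity of a spot is amplitude x 2 pi sigma^2 (px^2).
#'
#' Equal-valued neighbouring maxima are resolved deterministically: spots
#' are accepted in decreasing peak order (ties by row then column) subject
#' to the minimum separation.
#'
#' @param image 2-D numeric matrix (rows index y, columns x), e.g. from
#'   [averageInitialFrames()].
#' @param pixelSize um/px.
#' @param psfSigma nominal PSF sigma (um).
#' @param threshold absolute peak threshold above local background (counts);
#'   default `k` x robust noise sd.
#' @param k threshold multiplier when `threshold` is NULL (default 5).
#' @param minSeparation minimum centre separation (px, default 3).
#' @param channel label stored with the spots.
#' @return a [SpotList-class].
#' @export
detectSpots <- function(image, pixelSize, psfSigma, threshold = NULL, k = 5,
                        minSeparation = 3L, channel = "ch1") {
  if (!is.matrix(image) || !is.numeric(image)) stop("'image' must be a numeric matrix")
  if (length(image) == 0L) stop("empty image")
  if (all(image == max(image))) stop("degenerate (constant or saturated) image")
  bg <- stats::median(image)
  noise <- stats::mad(image)
  if (noise == 0 && is.null(threshold))
    noise <- stats::sd(image)
  if (is.null(threshold)) threshold <- k * noise
  if (threshold <= 0) stop("'threshold' must be positive")
  sigPx <- psfSigma / pixelSize
  w <- as.integer(minSeparation)
  mx <- maxFilter2(image, w)
  cand <- which(image == mx & (image - bg) > threshold, arr.ind = TRUE)
  spots <- data.frame(channel = character(0), x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), integrated = numeric(0),
                      sigma = numeric(0))
  if (nrow(cand)) {
    vals <- image[cand]
    ord <- order(-vals, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      prev <- cand[keep, , drop = FALSE]
      d2 <- (prev[, 1] - cand[i, 1])^2 + (prev[, 2] - cand[i, 2])^2
      if (all(d2 >= minSeparation^2)) keep[i] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
    fits <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand)))
      fits[[i]] <- .fitGaussianSpot(image, cand[i, 1], cand[i, 2], sigPx)
    fits <- fits[!vapply(fits, is.null, TRUE)]
    if (length(fits)) {
      spots <- data.frame(
        channel = channel,
        # pixel (1,1) centre is (0,0) um; columns are x, rows are y
        x = vapply(fits, function(f) (f$colPx - 1) * pixelSize, 0),
        y = vapply(fits, function(f) (f$rowPx - 1) * pixelSize, 0),
        amplitude = vapply(fits, function(f) f$A, 0),
        integrated = vapply(fits, function(f) f$A * 2 * pi * f$sigmaPx^2, 0),
        sigma = vapply(fits, function(f) f$sigmaPx * pixelSize, 0)
      )
      spots <- spots[spots$integrated > 0, , drop = FALSE]
    }
  }
  # spots within 3 px of the border cannot be fitted (7x7 window), so the
  # area actually surveyed is the interior
  effArea <- max(nrow(image) - 6L, 0L) * max(ncol(image) - 6L, 0L) * pixelSize^2
  new("SpotList", spots = spots,
      metadata = list(threshold = threshold, k = if (is.null(threshold)) k else NA,
                      background = bg, noiseSd = noise,
                      minSeparation = minSeparation, pixelSize = pixelSize,
                      psfSigma = psfSigma, effectiveArea = effArea))
}

#' Spot density of a field
#'
#' @param spotlist a [SpotList-class].
#' @param fieldArea field area (um^2), > 0; defaults to the effective
#'   (fittable, border-excluded) area recorded at detection time.
#' @return spots/um^2.
#' @export
countSpotDensity <- function(spotlist, fieldArea = NULL) {
  stopifnot(is(spotlist, "SpotList"))
  if (is.null(fieldArea)) fieldArea <- spotlist@metadata$effectiveArea
  if (is.null(fieldArea) || fieldArea <= 0) stop("'fieldArea' must be positive")
  nrow(spotlist@spots) / fieldArea
}

#' Total background-subtracted field intensity
#'
#' Sum over the field of (pixel - background), floored at 0 per pixel.
#'
#' @param image 2-D numeric matrix.
#' @param background background level per pixel (counts), e.g. estimated
#'   from a blank region or blank fixture.
#' @return total intensity (counts).
#' @export
measureTotalIntensity <- function(image, background) {
  if (!is.matrix(image)) stop("'image' must be a matrix")
  sum(pmax(image - background, 0))
}

#' Count vesicle-protein interactions by thresholded spot counting
#'
#' Detects spots and counts those whose integrated intensity is at or above
#' `vpiThreshold`. Each qualifying spot counts exactly once regardless of
#' its brightness, making the count robust to labelling heterogeneity and
#' dim fluorescent contaminants.
#'
#' @inheritParams detectSpots
#' @param vpiThreshold integrated-intensity threshold (counts).
#' @param fieldArea field area (um^2) for the density; derived from the
#'   image when omitted.
#' @param ... passed to [detectSpots()].
#' @return list with `count`, `density` (counts/um^2) and the underlying
#'   [SpotList-class] (`spots`).
#' @export
countVPI <- function(image, pixelSize, psfSigma, vpiThreshold,
                     fieldArea = NULL, ...) {
  sl <- detectSpots(image, pixelSize, psfSigma, ...)
  if (is.null(fieldArea))
    fieldArea <- prod(dim(image)) * pixelSize^2
  qual <- sl@spots$integrated >= vpiThreshold
  list(count = sum(qual), density = sum(qual) / fieldArea,
       spots = new("SpotList", spots = sl@spots[qual, , drop = FALSE],
                   metadata = c(sl@metadata, vpiThreshold = vpiThreshold)))
}
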