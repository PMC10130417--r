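# Two-channel colocalization: crosstalk estimation and correction, spot
# matching, chance baselines, enrichment and per-class bound fractions.

# Aperture photometry: background-subtracted sum in a disc of radius rad px
# around each (x, y) um position.
.apertureIntensity <- function(image, xUm, yUm, pixelSize, rad = 3L) {
  bg <- stats::median(image)
  nr <- nrow(image); nc <- ncol(image)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  vapply(seq_along(xUm), function(i) {
    r0 <- round(yUm[i] / pixelSize) + 1L
    c0 <- round(xUm[i] / pixelSize) + 1L
    rr <- r0 + off$dr; cc <- c0 + off$dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    sum(image[cbind(rr[ok], cc[ok])] - bg)
  }, 0)
}

#' Measure spot amplitudes at known positions
#'
#' Linear least-squares amplitude of a fixed-shape Gaussian (sigma =
#' psfSigma) at given positions: A = sum(g (z - local median)) / sum(g^2)
#' over a 7x7 px window. Unbiased under symmetric noise and robust to a
#' uniform background shift, unlike an aperture sum; used to quantify
#' residual bleed-through at source-spot locations.
#'
#' @param image 2-D numeric matrix.
#' @param x,y positions (um).
#' @param pixelSize um/px.
#' @param psfSigma Gaussian sigma (um).
#' @return numeric amplitudes (counts; NA where the window leaves the
#'   field).
#' @export
spotAmplitudeAt <- function(image, x, y, pixelSize, psfSigma) {
  sig <- psfSigma / pixelSize
  w <- 3L
  nr <- nrow(image); nc <- ncol(image)
  vapply(seq_along(x), function(i) {
    cpx <- x[i] / pixelSize + 1; rpx <- y[i] / pixelSize + 1
    r0 <- round(rpx); c0 <- round(cpx)
    if (r0 - w < 1 || r0 + w > nr || c0 - w < 1 || c0 + w > nc)
      return(NA_real_)
    rows <- (r0 - w):(r0 + w); cols <- (c0 - w):(c0 + w)
    z <- image[rows, cols]
    g <- outer(exp(-(rows - rpx)^2 / (2 * sig^2)),
               exp(-(cols - cpx)^2 / (2 * sig^2)))
    sum(g * (z - stats::median(z))) / sum(g^2)
  }, 0)
}

#' Estimate the inter-channel crosstalk matrix
#'
#' For each calibration stack containing a single pure fluorescent species
#' (named by its home channel), spots are detected in the home channel and
#' the bleed coefficient into every other channel is the median over spots
#' of (destination aperture intensity / source aperture intensity).
#'
#' @param stacks named list of [ImageStack-class] objects; names identify
#'   each stack's pure species / home channel, and every stack must carry
#'   all channels.
#' @param psfSigma nominal PSF sigma (um) for detection.
#' @param minSpots minimum spots per calibration stack (default 20).
#' @param ... passed to [detectSpots()].
#' @return crosstalk matrix (rows: source, cols: destination), unit
#'   diagonal, off-diagonals clamped at 0.
#' @export
estimateCrosstalk <- function(stacks, psfSigma, minSpots = 20L, ...) {
  chans <- channelNames(stacks[[1]])
  stopifnot(all(names(stacks) %in% chans))
  beta <- diag(length(chans))
  dimnames(beta) <- list(src = chans, dst = chans)
  for (src in names(stacks)) {
    st <- stacks[[src]]
    nFr <- dim(channelData(st, 1L))[1]
    imgs <- lapply(chans, function(ch) averageInitialFrames(st, min(10L, nFr), ch))
    names(imgs) <- chans
    sl <- detectSpots(imgs[[src]], st@pixelSize, psfSigma, channel = src, ...)
    sp <- spots(sl)
    if (nrow(sp) < minSpots)
      stop(sprintf("insufficient statistics: %d spots in '%s' calibration stack (>= %d required)",
                   nrow(sp), src, minSpots))
    srcI <- .apertureIntensity(imgs[[src]], sp$x, sp$y, st@pixelSize)
    ok <- srcI > 0
    for (dst in setdiff(chans, src)) {
      dstI <- .apertureIntensity(imgs[[dst]], sp$x, sp$y, st@pixelSize)
      beta[src, dst] <- max(0, stats::median(dstI[ok] / srcI[ok]))
    }
  }
  beta
}

#' Correct inter-channel crosstalk by linear unmixing
#'
#' Observed pixel vectors obey obs = t(beta) %*% true (sources mix into
#' destinations); each pixel of each frame is unmixed by the matrix inverse
#' after removing the camera offset, negative results are floored at 0, and
#' the offset is restored.
#'
#' @param stack an [ImageStack-class].
#' @param beta crosstalk matrix (rows: source, cols: destination); must be
#'   invertible.
#' @param offset camera offset to remove before unmixing (counts).
#' @param floor clamp negative unmixed intensities at 0 (default TRUE, the
#'   physical convention for counting and display). Flooring rectifies
#'   noise around dim features, so quantitative residual photometry should
#'   use `floor = FALSE`.
#' @return a corrected [ImageStack-class].
#' @export
correctCrosstalk <- function(stack, beta, offset = 0, floor = TRUE) {
  stopifnot(is(stack, "ImageStack"))
  nch <- length(stack@channels)
  if (nrow(beta) != nch || ncol(beta) != nch)
    stop("crosstalk matrix dimension must match the channel count")
  inv <- tryCatch(solve(t(beta)), error = function(e)
    stop("crosstalk matrix is not invertible"))
  dims <- dim(stack@channels[[1]])
  flat <- vapply(stack@channels, function(a) as.vector(a) - offset,
                 numeric(prod(dims)))
  un <- flat %*% t(inv)
  if (floor) un[un < 0] <- 0
  out <- lapply(seq_len(nch), function(c) array(un[, c] + offset, dim = dims))
  names(out) <- names(stack@channels)
  new("ImageStack", channels = out, pixelSize = stack@pixelSize,
      frameInterval = stack@frameInterval)
}

#' Match spots across two channels
#'
#' One-to-one greedy matching by ascending pair distance among all pairs
#' within `matchRadius`; ties are broken deterministically by spot index.
#' The chance-expected colocalized fraction for independent channels,
#' 1 - exp(-rho_B pi r^2), is reported alongside (not subtracted).
#'
#' @param spotsA,spotsB [SpotList-class] objects or data.frames with x, y
#'   columns (um), from the same field and coordinate convention.
#' @param matchRadius matching radius (um); default 0.216 um (2 px), the
#'   standard diffraction-limited co-detection radius.
#' @param fieldArea field area (um^2) for the chance baseline.
#' @return a [ColocalizationResult-class].
#' @export
matchSpots <- function(spotsA, spotsB, matchRadius = 0.216, fieldArea) {
  getXY <- function(s) {
    if (is(s, "SpotList")) s <- s@spots
    as.matrix(s[, c("x", "y")])
  }
  A <- getXY(spotsA); B <- getXY(spotsB)
  if (fieldArea <= 0) stop("'fieldArea' must be positive")
  nA <- nrow(A); nB <- nrow(B)
  pairs <- data.frame(idxA = integer(0), idxB = integer(0), distance = numeric(0))
  if (nA && nB) {
    dx <- outer(A[, 1], B[, 1], "-")
    dy <- outer(A[, 2], B[, 2], "-")
    dd <- sqrt(dx^2 + dy^2)
    idx <- which(dd <= matchRadius, arr.ind = TRUE)
    if (nrow(idx)) {
      ord <- order(dd[idx], idx[, 1], idx[, 2])
      idx <- idx[ord, , drop = FALSE]
      usedA <- logical(nA); usedB <- logical(nB)
      outA <- integer(0); outB <- integer(0); outD <- numeric(0)
      for (i in seq_len(nrow(idx))) {
        a <- idx[i, 1]; b <- idx[i, 2]
        if (!usedA[a] && !usedB[b]) {
          usedA[a] <- TRUE; usedB[b] <- TRUE
          outA <- c(outA, a); outB <- c(outB, b); outD <- c(outD, dd[a, b])
        }
      }
      pairs <- data.frame(idxA = outA, idxB = outB, distance = outD)
    }
  }
  rhoB <- nB / fieldArea
  new("ColocalizationResult",
      nA = nA, nB = nB, nMatched = nrow(pairs),
      fractionA = if (nA) nrow(pairs) / nA else NA_real_,
      fractionB = if (nB) nrow(pairs) / nB else NA_real_,
      chanceFraction = 1 - exp(-rhoB * pi * matchRadius^2),
      matchRadius = matchRadius, pairs = pairs)
}

#' Fold enrichment of a colocalized fraction over a control
#'
#' Either pass the two fractions directly (plain ratio, no CI), or pass hit
#' and total counts per condition for a seeded bootstrap CI over spots.
#'
#' @param fractionTarget,fractionControl fractions (mode 1).
#' @param hitsTarget,nTarget,hitsControl,nControl counts (mode 2).
#' @param nBoot bootstrap resamples.
#' @param seed integer seed.
#' @return list with `fold` and `ci` (NA without counts).
#' @export
enrichmentFold <- function(fractionTarget = NULL, fractionControl = NULL,
                           hitsTarget = NULL, nTarget = NULL,
                           hitsControl = NULL, nControl = NULL,
                           nBoot = 1000L, seed = 1L) {
  if (!is.null(hitsTarget)) {
    fractionTarget <- hitsTarget / nTarget
    fractionControl <- hitsControl / nControl
  }
  if (is.null(fractionTarget) || is.null(fractionControl))
    stop("supply either fractions or hit/total counts")
  if (fractionControl <= 0) stop("'fractionControl' must be positive")
  fold <- fractionTarget / fractionControl
  ci <- c(NA_real_, NA_real_)
  if (!is.null(hitsTarget)) {
    tVec <- c(rep(1, hitsTarget), rep(0, nTarget - hitsTarget))
    cVec <- c(rep(1, hitsControl), rep(0, nControl - hitsControl))
    boot <- withSubSeed(seed, "enrichment-boot", {
      vapply(seq_len(nBoot), function(i) {
        fc <- mean(sample(cVec, replace = TRUE))
        if (fc == 0) NA_real_ else mean(sample(tVec, replace = TRUE)) / fc
      }, 0)
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  list(fold = fold, ci = ci)
}

#' Vesicle-bound fraction per spot class
#'
#' For each protein spot class (single-species vs colocalized), the
#' fraction of class members with at least one vesicle within the match
#' radius.
#'
#' @param vesicleSpots vesicle positions ([SpotList-class] or data.frame
#'   with x, y in um).
#' @param classASpots single-species protein spots.
#' @param classABSpots colocalized protein spots.
#' @param matchRadius um.
#' @return named numeric: `aOnly` and `coloc` bound fractions.
#' @export
vesicleBoundFraction <- function(vesicleSpots, classASpots, classABSpots,
                                 matchRadius = 0.216) {
  getXY <- function(s) {
    if (is(s, "SpotList")) s <- s@spots
    as.matrix(s[, c("x", "y")])
  }
  V <- getXY(vesicleSpots)
  frac <- function(M) {
    if (!nrow(M)) return(NA_real_)
    if (!nrow(V)) return(0)
    hits <- vapply(seq_len(nrow(M)), function(i) {
      any((V[, 1] - M[i, 1])^2 + (V[, 2] - M[i, 2])^2 <= matchRadius^2)
    }, TRUE)
    mean(hits)
  }
  c(aOnly = frac(getXY(classASpots)), coloc = frac(getXY(classABSpots)))
}

#' Ratiometric bound fraction and molar ratio
#'
#' Expresses a background-corrected co-signal fraction f as a 1:N molar
#' ratio with N = round(1/f); e.g. f = 0.07 gives 1:14.
#'
#' @param fraction bound fraction in [0, 1].
#' @return list with `fraction`, `ratioN` (integer N, NA at f = 0) and
#'   `ratio` ("1:N" string).
#' @export
ratiometricBoundFraction <- function(fraction) {
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]")
  n <- if (fraction > 0) as.integer(round(1 / fraction)) else NA_integer_
  list(fraction = fraction, ratioN = n,
       ratio = if (is.na(n)) NA_character_ else paste0("1:", n))
}

#' Compare spot-intensity distributions between classes
#'
#' Histograms per class plus a two-sided rank-based location comparison
#' (Wilcoxon rank-sum statistic) with a seeded permutation p-value.
#'
#' @param intensity numeric spot intensities.
#' @param class factor/character class labels (exactly two classes, >= 30
#'   spots each).
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return list with `histograms` (per class), `statistic` (rank-sum of
#'   class 2), `p.value`, and class names.
#' @export
intensityByClass <- function(intensity, class, nPerm = 1000L, seed = 1L) {
  class <- as.character(class)
  lv <- sort(unique(class))
  if (length(lv) < 2L) stop("need two classes; got one")
  if (length(lv) > 2L) stop("exactly two classes supported")
  n1 <- sum(class == lv[1]); n2 <- sum(class == lv[2])
  if (min(n1, n2) < 30L) stop("need >= 30 spots per class")
  r <- rank(intensity)
  obs <- sum(r[class == lv[2]])
  perm <- withSubSeed(seed, "intensity-perm", {
    vapply(seq_len(nPerm), function(i) sum(r[sample(class) == lv[2]]), 0)
  })
  # two-sided permutation p-value with add-one correction
  p <- (1 + sum(abs(perm - mean(perm)) >= abs(obs - mean(perm)))) / (nPerm + 1)
  brk <- pretty(range(intensity), 30)
  list(histograms = lapply(lv, function(l)
         graphics::hist(intensity[class == l], breaks = brk, plot = FALSE)),
       classes = lv, statistic = obs, p.value = p)
}
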