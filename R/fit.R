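# Weighted nonlinear least-squares fitting of the binding models, with
# multi-start initialization in log-parameter space, bootstrap confidence
# intervals and AICc model selection.
#
# Identifiability: on a density-axis curve measured at a single vesicle
# concentration only the products alpha * V/(V + Kd) are identifiable, so
# the capture-efficiency scale alpha is fixed (default 1) unless freed
# explicitly; likewise the cooperation reach d is a geometric property of
# the vesicle (contact footprint) and is fixed at its known value by
# default, with fitD = TRUE to free it.

# Model definitions on the transformed (optimizer) scale.
.fitDef <- function(kind, curve, conc, d = 0.1, alpha = 1,
                    freeAlpha = FALSE, fitD = FALSE) {
  x <- curve@x; y <- curve@y
  switch(kind,
    langmuir = {
      if (curve@xKind != "density")
        stop("Langmuir fits need a density-axis curve")
      if (is.na(conc)) stop("vesicle concentration 'conc' required")
      par <- c(logKd = 0)
      lower <- c(logKd = -4); upper <- c(logKd = 4)
      if (freeAlpha) { par <- c(par, logAlpha = -0.5)
        lower <- c(lower, logAlpha = -6); upper <- c(upper, logAlpha = 0) }
      list(par = par, lower = lower, upper = upper,
        starts = function(ns) {
          g <- seq(-3, 3, length.out = ns)
          m <- cbind(logKd = g)
          if (freeAlpha) m <- cbind(m, logAlpha = rep(-0.5, ns))
          m
        },
        predict = function(p, x) {
          a <- if (freeAlpha) 10^p[["logAlpha"]] else alpha
          a * x * .occupancy(conc, 10^p[["logKd"]])
        },
        toModel = function(p) langmuirModel(10^p[["logKd"]],
          if (freeAlpha) 10^p[["logAlpha"]] else alpha),
        natural = function(p) {
          est <- c(kd = 10^p[["logKd"]])
          if (freeAlpha) est <- c(est, alpha = 10^p[["logAlpha"]])
          est
        })
    },
    cooperative = {
      if (curve@xKind != "density")
        stop("cooperative fits need a density-axis curve")
      if (is.na(conc)) stop("vesicle concentration 'conc' required")
      par <- c(logKd1 = 1, logKd2 = -1)
      lower <- c(logKd1 = -4, logKd2 = -4); upper <- c(logKd1 = 4, logKd2 = 4)
      if (fitD) { par <- c(par, logD = log10(d))
        lower <- c(lower, logD = log10(0.02)); upper <- c(upper, logD = log10(0.5)) }
      list(par = par, lower = lower, upper = upper,
        starts = function(ns) {
          g1 <- seq(-2, 3, length.out = ns)
          g2 <- seq(3, -2, length.out = ns)  # opposite sweep: kd2 < kd1 half
          m <- cbind(logKd1 = g1, logKd2 = pmin(g1, g2) - 1)
          if (fitD) m <- cbind(m, logD = rep(log10(d), ns))
          m
        },
        predict = function(p, x) {
          dd <- if (fitD) 10^p[["logD"]] else d
          s <- siteDensities(x, dd)
          alpha * (s$s1 * .occupancy(conc, 10^p[["logKd1"]]) +
                   s$s2 * .occupancy(conc, 10^p[["logKd2"]]))
        },
        toModel = function(p) cooperativeModel(10^p[["logKd1"]], 10^p[["logKd2"]],
          if (fitD) 10^p[["logD"]] else d, alpha),
        natural = function(p) {
          est <- c(kd1 = 10^p[["logKd1"]], kd2 = 10^p[["logKd2"]])
          if (fitD) est <- c(est, d = 10^p[["logD"]])
          est
        })
    },
    hill = {
      if (!curve@xKind %in% c("concentration", "density"))
        stop("Hill fits need a concentration-axis curve")
      ymax <- max(y); xmid <- stats::median(x[x > 0])
      par <- c(logNmax = log10(max(ymax, 1e-12)), logKhalf = log10(xmid), n = 1.5)
      lower <- c(logNmax = par[["logNmax"]] - 3,
                 logKhalf = log10(min(x[x > 0])) - 2, n = 0.2)
      upper <- c(logNmax = par[["logNmax"]] + 3,
                 logKhalf = log10(max(x)) + 2, n = 6)
      list(par = par, lower = lower, upper = upper,
        starts = function(ns) cbind(logNmax = rep(par[["logNmax"]], ns),
                                    logKhalf = seq(lower[["logKhalf"]] + 1,
                                                   upper[["logKhalf"]] - 1,
                                                   length.out = ns),
                                    n = seq(0.5, 3.5, length.out = ns)),
        predict = function(p, x) hillN(x, hillModel(10^p[["logNmax"]],
                                                    10^p[["logKhalf"]], p[["n"]])),
        toModel = function(p) hillModel(10^p[["logNmax"]], 10^p[["logKhalf"]], p[["n"]]),
        natural = function(p) c(nmax = 10^p[["logNmax"]],
                                khalf = 10^p[["logKhalf"]], n = p[["n"]]))
    },
    ic50 = {
      if (curve@xKind != "dose") stop("IC50 fits need a dose-axis curve")
      ymax <- max(y); ymin <- min(y)
      pos <- x[x > 0]
      par <- c(n0 = ymax, nbg = ymin, logIc50 = log10(stats::median(pos)), h = 1)
      lower <- c(n0 = 0, nbg = 0, logIc50 = log10(min(pos)) - 2, h = 0.2)
      upper <- c(n0 = 2 * ymax + 1e-9, nbg = ymax + 1e-9,
                 logIc50 = log10(max(pos)) + 2, h = 10)
      list(par = par, lower = lower, upper = upper,
        starts = function(ns) cbind(n0 = rep(ymax, ns), nbg = rep(ymin, ns),
                                    logIc50 = seq(lower[["logIc50"]] + 1,
                                                  upper[["logIc50"]] - 1,
                                                  length.out = ns),
                                    h = rep(1, ns)),
        predict = function(p, x) p[["nbg"]] + (p[["n0"]] - p[["nbg"]]) /
          (1 + (x / 10^p[["logIc50"]])^p[["h"]]),
        toModel = function(p) inhibitionModel(p[["n0"]], min(p[["nbg"]], p[["n0"]] * 0.999),
                                              10^p[["logIc50"]], p[["h"]]),
        natural = function(p) c(n0 = p[["n0"]], nbg = p[["nbg"]],
                                ic50 = 10^p[["logIc50"]], h = p[["h"]]))
    },
    kinetic = {
      if (curve@xKind != "time") stop("kinetic fits need a time-axis curve")
      ymax <- max(y)
      par <- c(logNeq = log10(max(ymax, 1e-12)), logKobs = -2)
      lower <- c(logNeq = par[["logNeq"]] - 3, logKobs = -6)
      upper <- c(logNeq = par[["logNeq"]] + 3, logKobs = 2)
      list(par = par, lower = lower, upper = upper,
        starts = function(ns) cbind(logNeq = rep(par[["logNeq"]], ns),
                                    logKobs = seq(-4, 0, length.out = ns)),
        predict = function(p, x) 10^p[["logNeq"]] * (1 - exp(-10^p[["logKobs"]] * x)),
        toModel = function(p) kineticModel(kon = 0, koff = 10^p[["logKobs"]],
                                           neq = 10^p[["logNeq"]]),
        natural = function(p) c(neq = 10^p[["logNeq"]], kobs = 10^p[["logKobs"]]))
    },
    stop(sprintf("unknown model kind '%s'; supported: langmuir, cooperative, hill, ic50, kinetic",
                 kind))
  )
}

.aicc <- function(rss, n, p) {
  k <- p + 1  # + residual variance
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# One weighted NLS solve from a given start; returns list(par, rss, ok).
# `wts` is either a numeric weight vector or a function of the prediction
# (model-based weights, recomputed every iteration).
.solveNls <- function(def, start, xs, ym, wts) {
  resid <- function(p) {
    names(p) <- names(def$par)
    pred <- def$predict(p, xs)
    w <- if (is.function(wts)) wts(pred) else wts
    sqrt(w) * (pred - ym)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = def$lower, upper = def$upper,
                       fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(ok = FALSE))
  p <- fit$par; names(p) <- names(def$par)
  list(ok = fit$info %in% 1:4, par = p, rss = sum(fit$fvec^2))
}

#' Fit a binding model to a binding curve
#'
#' Weighted nonlinear least squares on replicate-level means (weights =
#' inverse replicate variances when replicates are present), with
#' equilibrium constants optimized in log space and multi-start
#' initialization (best residual-sum-of-squares start wins). Bootstrap 95%
#' CIs are obtained by resampling replicates within each level and
#' refitting.
#'
#' @param curve a [BindingCurve-class].
#' @param kind one of "langmuir", "cooperative", "hill", "ic50", "kinetic".
#' @param conc vesicle concentration (pM) for density-axis models; default
#'   taken from the curve.
#' @param d cooperation reach (um), fixed unless `fitD`.
#' @param alpha capture-efficiency scale, fixed unless `freeAlpha`
#'   (Langmuir only).
#' @param fitD free the reach parameter (cooperative).
#' @param freeAlpha free the capture efficiency (Langmuir).
#' @param nStarts number of seeded starts (>= 5 recommended).
#' @param nBoot bootstrap draws for CIs (0 disables).
#' @param seed integer seed for starts and bootstrap.
#' @param weights weighting scheme for replicate-level means: "pooled-cv"
#'   (inverse variances from a pooled constant-CV model of the replicate
#'   scatter; the default, robust to noisy small-sample variances),
#'   "replicate-sd" (raw inverse sample variances), or "none".
#' @return a [FitResult-class].
#' @export
fitModel <- function(curve, kind, conc = curve@conc, d = 0.1, alpha = 1,
                     fitD = FALSE, freeAlpha = FALSE, nStarts = 5L,
                     nBoot = 1000L, seed = 1L,
                     weights = c("pooled-cv", "replicate-sd", "none")) {
  stopifnot(is(curve, "BindingCurve"))
  def <- .fitDef(kind, curve, conc, d = d, alpha = alpha,
                 freeAlpha = freeAlpha, fitD = fitD)
  sm <- curveSummary(curve)
  p <- length(def$par)
  if (nrow(sm) < p + 2L)
    stop(sprintf("need >= %d distinct x values for a %d-parameter '%s' fit; got %d",
                 p + 2L, p, kind, nrow(sm)))
  useW <- all(is.finite(sm$sd)) && all(sm$sd > 0) && all(sm$n >= 2L)
  weights <- match.arg(weights)
  if (weights == "pooled-cv" && useW) {
    # Replicate scatter is multiplicative (constant CV), so per-level
    # variances follow a pooled-CV model, which is far more stable than
    # 5-replicate sample variances. Weights are model-based (recomputed
    # from the prediction at every iteration, quasi-likelihood style) to
    # avoid the downward bias of weighting by observed means.
    pos <- sm$mean > 0
    cv <- sqrt(mean((sm$sd[pos] / sm$mean[pos])^2))
    floorSig <- cv * min(sm$mean[pos]) / 2
    nrep <- sm$n
    wts <- function(pred) nrep / pmax(cv * pred, floorSig)^2
  } else if (weights == "replicate-sd" && useW) {
    wts <- sm$n / sm$sd^2
  } else {
    useW <- FALSE
    wts <- rep(1, nrow(sm))
  }
  starts <- rbind(def$par, def$starts(max(nStarts - 1L, 1L)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- starts[i, ]; names(st) <- names(def$par)
    sol <- .solveNls(def, st, sm$x, sm$mean, wts)
    if (sol$ok && (is.null(best) || sol$rss < best$rss)) best <- sol
  }
  if (is.null(best)) {
    return(new("FitResult", model = def$toModel(def$par), kind = kind,
               estimates = def$natural(def$par),
               ci = matrix(numeric(0), nrow = 0, ncol = 2),
               rss = NA_real_, aicc = Inf, converged = FALSE,
               flags = "non-convergent", nObs = nrow(sm),
               seed = as.integer(seed), details = list()))
  }
  flags <- character(0)
  atLo <- abs(best$par - def$lower) < 1e-6
  atHi <- abs(best$par - def$upper) < 1e-6
  if (any(atLo | atHi))
    flags <- c(flags, paste0("at-bound:", paste(names(def$par)[atLo | atHi],
                                                collapse = ",")))
  ci <- matrix(numeric(0), nrow = 0, ncol = 2)
  bootDraws <- NULL
  if (nBoot > 0L) {
    bootDraws <- withSubSeed(seed, "fit-boot", {
      draws <- matrix(NA_real_, nBoot, p, dimnames = list(NULL, names(def$par)))
      levIdx <- lapply(sm$x, function(v) which(curve@x == v))
      for (bI in seq_len(nBoot)) {
        ymb <- vapply(levIdx, function(ii)
          mean(curve@y[sample(ii, replace = TRUE)]), 0)
        sol <- .solveNls(def, best$par, sm$x, ymb, wts)
        if (sol$ok) draws[bI, ] <- sol$par
      }
      draws
    })
    qs <- apply(bootDraws, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    # transform CI to the natural scale per parameter
    ci <- t(vapply(seq_len(p), function(j) {
      lohi <- qs[, j]
      nm <- names(def$par)[j]
      if (startsWith(nm, "log")) 10^lohi else lohi
    }, numeric(2)))
    rownames(ci) <- names(def$natural(best$par))
    colnames(ci) <- c("lo", "hi")
  }
  new("FitResult", model = def$toModel(best$par), kind = kind,
      estimates = def$natural(best$par), ci = ci, rss = best$rss,
      aicc = .aicc(best$rss, nrow(sm), p), converged = TRUE, flags = flags,
      nObs = nrow(sm), seed = as.integer(seed),
      details = list(par = best$par, weights = wts, weighted = useW,
                     boot = bootDraws))
}

#' Select between candidate adsorption models by AICc
#'
#' Fits each candidate and selects the minimum-AICc model, requiring an
#' AICc improvement of more than 2 before a model with more parameters is
#' preferred over one with fewer (ties go to the smaller model). Candidates
#' with too few distinct x values for their parameter count are excluded by
#' an identifiability guard.
#'
#' @param curve a [BindingCurve-class] (density axis).
#' @param candidates model kinds to compare.
#' @param ... passed to [fitModel()] (e.g. `conc`, `d`).
#' @return a [ModelComparison-class].
#' @export
selectModel <- function(curve, candidates = c("langmuir", "cooperative"), ...) {
  fits <- list()
  for (k in candidates) {
    fits[[k]] <- tryCatch(fitModel(curve, k, nBoot = 0L, ...),
                          error = function(e) e)
  }
  guard <- vapply(fits, function(f) is(f, "FitResult"), TRUE)
  rows <- lapply(names(fits), function(k) {
    f <- fits[[k]]
    if (is(f, "FitResult"))
      data.frame(kind = k, nPar = length(f@estimates), rss = f@rss,
                 aicc = f@aicc, converged = f@converged)
    else
      data.frame(kind = k, nPar = NA_integer_, rss = NA_real_, aicc = Inf,
                 converged = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$dAicc <- tab$aicc - min(tab$aicc)
  incomplete <- any(!tab$converged & guard)
  fitted <- tab[tab$converged, , drop = FALSE]
  selected <- NA_character_
  rule <- "min AICc; dAICc > 2 required to prefer more parameters; ties to fewer"
  if (nrow(fitted)) {
    fitted <- fitted[order(fitted$aicc, fitted$nPar), , drop = FALSE]
    bestRow <- fitted[1, ]
    smaller <- fitted[fitted$nPar < bestRow$nPar, , drop = FALSE]
    if (nrow(smaller) && min(smaller$aicc) - bestRow$aicc <= 2)
      bestRow <- smaller[which.min(smaller$aicc), ]
    selected <- bestRow$kind
  }
  if (incomplete) rule <- paste(rule, "(incomplete: a candidate failed to converge)")
  new("ModelComparison", table = tab, selected = selected, rule = rule)
}

#' Fit a sigmoidal IC50 inhibition curve
#'
#' Requires >= 5 doses spanning at least two decades. Data that increase
#' with dose are not an inhibition experiment; such fits are flagged
#' "non-inhibitory" and marked non-converged.
#'
#' @param curve a dose-axis [BindingCurve-class].
#' @param nBoot bootstrap draws for the IC50 CI.
#' @param seed integer seed.
#' @return a [FitResult-class].
#' @export
fitIC50 <- function(curve, nBoot = 1000L, seed = 1L) {
  stopifnot(is(curve, "BindingCurve"), curve@xKind == "dose")
  sm <- curveSummary(curve)
  pos <- sm$x[sm$x > 0]
  if (length(sm$x) < 5L) stop("need >= 5 doses")
  if (max(pos) / min(pos) < 100) stop("doses must span >= 2 decades")
  fr <- fitModel(curve, "ic50", nBoot = nBoot, seed = seed)
  rho <- stats::cor(sm$x, sm$mean, method = "spearman")
  if (is.finite(rho) && rho > 0.5) {
    fr@flags <- unique(c(fr@flags, "non-inhibitory"))
    fr@converged <- FALSE
  }
  fr
}
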