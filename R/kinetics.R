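#' @describeIn autocorrelation normalized ACF of one numeric trajectory.
#'
#' Mean-subtracted, variance-normalized sample autocorrelation with the
#' biased (1/N) estimator, the standard stable choice at long lags:
#' G(tau) = <dI(t) dI(t+tau)> / <dI^2>, so G(0) = 1 exactly.
#'
#' @param dt frame time in seconds.
#' @param lagMax maximum lag in frames (default one third of the length).
#' @export
setMethod("autocorrelation", "numeric", function(x, dt = 0.034,
                                                 lagMax = NULL, ...) {
  stopIfNot(length(x) >= 10, "trajectory must have at least 10 frames")
  stopIfNot(stats::var(x) > 0, "trajectory has zero variance")
  lagMax <- as.integer(lagMax %||% floor(length(x) / 3))
  a <- stats::acf(x, lag.max = lagMax, plot = FALSE, demean = TRUE,
                  type = "correlation")$acf[, 1, 1]
  methods::new("AcfCurve", lags = (0:lagMax) * dt, values = as.numeric(a),
               sem = numeric(0), nTrajectories = 1L)
})

#' @describeIn autocorrelation per-trajectory ACFs of a [TrajectorySet-class];
#'   returns a list of [AcfCurve-class] (trajectories with zero variance are
#'   dropped with a message).
#' @export
setMethod("autocorrelation", "TrajectorySet", function(x, lagMax = NULL, ...) {
  m <- intensities(x)
  ok <- apply(m, 2, stats::var) > 0
  if (!all(ok))
    message(sum(!ok), " zero-variance trajectories dropped")
  lapply(which(ok), function(j)
    autocorrelation(m[, j], dt = frameTime(x), lagMax = lagMax))
})

#' Average autocorrelation curves
#'
#' Per-lag mean and standard error over an ensemble of ACF curves computed
#' on the same lag grid.
#'
#' @param curves list of [AcfCurve-class] objects.
#' @return an [AcfCurve-class] with per-lag SEM.
#' @export
meanAcf <- function(curves) {
  stopIfNot(length(curves) >= 2, "need at least 2 curves to average")
  lags <- acfLags(curves[[1]])
  same <- vapply(curves, function(cv)
    length(acfLags(cv)) == length(lags) &&
      all(abs(acfLags(cv) - lags) < 1e-9), logical(1))
  stopIfNot(all(same), "curves must share one lag grid")
  m <- vapply(curves, acfValues, numeric(length(lags)))
  methods::new("AcfCurve", lags = lags, values = rowMeans(m),
               sem = apply(m, 1, stats::sd) / sqrt(length(curves)),
               nTrajectories = length(curves))
}

#' Decompose a mean ACF into short/medium/long components
#'
#' Fits the ACF beyond the first frame lag with single and double
#' exponential decays, \code{aM * exp(-tau/tauM) + aL * exp(-tau/tauL)},
#' selecting the double model when it improves the AIC. The amplitude
#' missing at lag zero is the short (sub-frame) component
#' \code{aS = 1 - aM - aL}, collecting per-frame noise and binding events
#' faster than the integration time; its uncertainty is taken from the
#' ensemble SEM at the first fitted lag.
#'
#' @param curve an [AcfCurve-class] (usually a mean curve).
#' @param fitStart first lag time (s) included in the fit; the default
#'   0.034 s skips only the zero-lag point of a 34-ms acquisition.
#' @param model \code{"auto"} (AIC selection), \code{"single"} or
#'   \code{"double"}.
#' @param weights \code{"sem"} weights residuals by 1/SEM^2 when the curve
#'   carries SEMs; \code{"none"} disables weighting.
#' @return an [AcfDecomposition-class].
#' @export
fitAcfDecomposition <- function(curve, fitStart = 0.034,
                                model = c("auto", "single", "double"),
                                weights = c("none", "sem")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  lags <- acfLags(curve); vals <- acfValues(curve)
  keep <- lags >= fitStart - 1e-12
  stopIfNot(sum(keep) >= 20, "need >= 20 lags beyond fitStart")
  tau <- lags[keep]; y <- vals[keep]
  dt <- lags[2] - lags[1]
  sem <- acfSem(curve)
  aSErr <- if (length(sem)) sem[which(keep)[1]] else NA_real_
  w <- if (weights == "sem" && length(sem) && all(sem[keep] > 0))
    1 / sem[keep]^2 else rep(1, length(y))

  # degenerate: no decay signal beyond lag zero
  if (all(abs(y) < 1e-8)) {
    return(methods::new("AcfDecomposition", aS = 1, aM = 0, aL = 0,
                        tauM = NA_real_, tauL = NA_real_,
                        aSErr = aSErr, aMErr = 0, aLErr = 0,
                        tauMErr = NA_real_, tauLErr = NA_real_,
                        model = "degenerate", fitStart = fitStart))
  }

  df <- data.frame(tau = tau, y = y)
  # crude log-linear initial decay estimate
  pos <- y > max(y) * 0.05 & y > 0
  tau0 <- if (sum(pos) >= 3)
    tryCatch(unname(-1 / stats::coef(stats::lm(log(y[pos]) ~ tau[pos]))[2]),
             error = function(e) NA_real_) else NA_real_
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(tau) / 3
  a0 <- max(min(y[1], 1), 1e-3)

  fitSingle <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-tau / t1), data = df, weights = w,
                      start = list(a = a0, t1 = tau0),
                      lower = c(0, dt / 10), upper = c(2, 100 * max(tau)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  fitDouble <- NULL
  if (model != "single") {
    starts <- list(
      list(aM = a0 * 0.4, tM = max(dt, tau0 / 4),
           aL = a0 * 0.6, tL = tau0 * 2),
      list(aM = a0 * 0.6, tM = max(dt, tau0 / 8),
           aL = a0 * 0.4, tL = tau0 * 4))
    for (st in starts) {
      fitDouble <- tryCatch(
        minpack.lm::nlsLM(y ~ aM * exp(-tau / tM) + aL * exp(-tau / tL),
                          data = df, weights = w, start = st,
                          lower = c(0, dt / 10, 0, dt / 10),
                          upper = c(2, 100 * max(tau), 2, 100 * max(tau)),
                          control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(fitDouble)) break
    }
  }

  useDouble <- switch(model,
    single = FALSE,
    double = { stopIfNot(!is.null(fitDouble), "double-exponential fit failed"); TRUE },
    auto = !is.null(fitDouble) &&
      (is.null(fitSingle) || stats::AIC(fitDouble) < stats::AIC(fitSingle)))

  if (useDouble) {
    co <- stats::coef(fitDouble)
    se <- tryCatch(summary(fitDouble)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 4))
    # order components so tauM < tauL
    if (co["tM"] > co["tL"]) {
      co <- co[c("aL", "tL", "aM", "tM")]
      names(co) <- c("aM", "tM", "aL", "tL")
      se <- se[c("aL", "tL", "aM", "tM")]
      names(se) <- c("aM", "tM", "aL", "tL")
    }
    aM <- unname(co["aM"]); aL <- unname(co["aL"])
    methods::new("AcfDecomposition", aS = 1 - aM - aL, aM = aM, aL = aL,
                 tauM = unname(co["tM"]), tauL = unname(co["tL"]),
                 aSErr = aSErr, aMErr = unname(se["aM"]),
                 aLErr = unname(se["aL"]), tauMErr = unname(se["tM"]),
                 tauLErr = unname(se["tL"]), model = "double",
                 fitStart = fitStart)
  } else {
    stopIfNot(!is.null(fitSingle),
              "exponential fit did not converge; inspect the input curve")
    co <- stats::coef(fitSingle)
    se <- tryCatch(summary(fitSingle)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    aL <- unname(co["a"])
    methods::new("AcfDecomposition", aS = 1 - aL, aM = 0, aL = aL,
                 tauM = NA_real_, tauL = unname(co["t1"]),
                 aSErr = aSErr, aMErr = 0, aLErr = unname(se["a"]),
                 tauMErr = NA_real_, tauLErr = unname(se["t1"]),
                 model = "single", fitStart = fitStart)
  }
}

#' Extract a focus-intensity trajectory from a burst stack
#'
#' Per-frame background-subtracted sum over a disk region of interest at a
#' fixed position: the frame background is estimated as the median of an
#' annulus from \code{roiRadiusPx} to \code{2 * roiRadiusPx} around the
#' focus and subtracted per pixel.
#'
#' @param stack 3D numeric array (rows x cols x frames) of camera counts.
#' @param position numeric length-2 focus position in um (x, y).
#' @param roiRadiusPx disk radius in pixels.
#' @param pixelSize um per pixel.
#' @param dt frame time (s).
#' @param cell optional [CellOutline-class] owning the focus. When given,
#'   the per-frame background is the median of in-cell pixels outside the
#'   disk, which tracks the bleaching of the diffuse unbound pool far
#'   better than the default annulus (an annulus around a focus in a
#'   narrow cell inevitably samples non-cell pixels).
#' @return a [TrajectorySet-class] with one measured trajectory.
#' @export
extractTrajectory <- function(stack, position, roiRadiusPx = 4,
                              pixelSize = 0.1, dt = 0.034, cell = NULL) {
  stopifnot(length(dim(stack)) == 3)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nf <- dim(stack)[3]
  jc <- position[1] / pixelSize + 0.5
  ic <- position[2] / pixelSize + 0.5
  rOut <- 2 * roiRadiusPx
  stopIfNot(jc - rOut >= 1 && jc + rOut <= nc &&
              ic - rOut >= 1 && ic + rOut <= nr,
            "ROI (including background annulus) exceeds the frame")
  js <- floor(jc - rOut):ceiling(jc + rOut)
  is <- floor(ic - rOut):ceiling(ic + rOut)
  dd <- outer((is - ic)^2, (js - jc)^2, "+")
  disk <- dd <= roiRadiusPx^2
  diskLin <- outer(is, (js - 1L) * nr, "+")[disk]
  if (is.null(cell)) {
    ann <- dd > roiRadiusPx^2 & dd <= rOut^2
    bgLin <- outer(is, (js - 1L) * nr, "+")[ann]
  } else {
    # clip the disk to the cell so the per-pixel background subtraction is
    # consistent for foci near the poles or membrane
    inCell <- pixelsInsideCell(cell, c(nr, nc), pixelSize)
    diskLin <- intersect(diskLin, inCell)
    stopIfNot(length(diskLin) >= 5, "focus ROI lies outside the cell")
    bgLin <- setdiff(inCell, diskLin)
    stopIfNot(length(bgLin) >= 10, "cell too small for background estimate")
  }
  frameStride <- as.double(nr) * nc
  vals <- vapply(seq_len(nf), function(f) {
    off <- (f - 1) * frameStride
    sum(stack[diskLin + off]) -
      stats::median(stack[bgLin + off]) * length(diskLin)
  }, numeric(1))
  methods::new("TrajectorySet",
               intensities = matrix(vals, ncol = 1), dt = dt,
               origin = "measured")
}

#' Plot an ACF curve with an optional decomposition overlay
#'
#' @param x an [AcfCurve-class].
#' @param y optionally an [AcfDecomposition-class] to overlay.
#' @param ... passed to [graphics::plot()].
#' @export
setMethod("plot", signature("AcfCurve", "ANY"), function(x, y, ...) {
  graphics::plot(acfLags(x), acfValues(x), type = "p", pch = 16, cex = 0.6,
                 xlab = "lag time (s)", ylab = "autocorrelation", ...)
  if (length(acfSem(x)))
    graphics::arrows(acfLags(x), acfValues(x) - acfSem(x),
                     acfLags(x), acfValues(x) + acfSem(x),
                     length = 0.01, angle = 90, code = 3, col = "grey60")
  if (!missing(y) && is(y, "AcfDecomposition") && y@model != "degenerate") {
    tt <- seq(y@fitStart, max(acfLags(x)), length.out = 200)
    yy <- y@aL * exp(-tt / y@tauL)
    if (y@model == "double") yy <- yy + y@aM * exp(-tt / y@tauM)
    graphics::lines(tt, yy, col = "firebrick", lwd = 2)
  }
  invisible(x)
})
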