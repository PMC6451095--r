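# Shared fixtures and scoring helpers, all built in code at test time.

# A single-channel time-lapse configuration with static stoichiometry and
# uniform focus placement, used by the detection round-trip tests.
uniformTimelapseConfig <- function(nCells, seed, duration = 10,
                                   focusDensity = 0.79) {
  timelapseConfig(
    nCells = as.integer(nCells), duration = duration, interval = 10,
    seed = seed, channels = "A", focusDensity = c(A = focusDensity),
    stoichiometrySchedule = list(A = list(before = 1L, after = 1L,
                                          switchTime = Inf)),
    spatialMode = list(A = list(before = "uniform", after = "uniform",
                                switchTime = Inf)))
}

# Detected-versus-ground-truth scoring: recall (fraction of true foci with a
# detection within matchRadiusUm), false-positive rate (detections with no
# true focus within the radius) and the median centroid error of matches.
scoreDetections <- function(detected, truth, matchRadiusUm = 0.2) {
  stopifnot(nrow(truth) > 0)
  dists <- function(x, y) sqrt((detected$x_um - x)^2 + (detected$y_um - y)^2)
  rec <- vapply(seq_len(nrow(truth)), function(k)
    nrow(detected) > 0 && any(dists(truth$x_um[k], truth$y_um[k]) <=
                                matchRadiusUm), logical(1))
  fp <- if (nrow(detected)) vapply(seq_len(nrow(detected)), function(k)
    !any(sqrt((truth$x_um - detected$x_um[k])^2 +
                (truth$y_um - detected$y_um[k])^2) <= matchRadiusUm),
    logical(1)) else logical(0)
  err <- vapply(which(rec), function(k)
    min(dists(truth$x_um[k], truth$y_um[k])), numeric(1))
  list(recall = mean(rec), fpRate = if (length(fp)) mean(fp) else 0,
       medianErrUm = if (length(err)) stats::median(err) else NA_real_)
}

# Detect foci in every field of a synthetic time lapse at one time index.
detectAllFields <- function(tl, timeIndex = 1L, channel = "A", ...) {
  ct <- tl@cellTable
  out <- NULL
  for (fd in seq_along(tl@frames)) {
    ids <- unique(ct$cell_id[ct$field == fd])
    cset <- methods::new("CellSet", cells = Filter(
      function(x) cellId(x) %in% ids, tl@cells[[timeIndex]]@cells))
    fs <- suppressWarnings(detectFoci(
      tl@frames[[fd]][[timeIndex]][[channel]], cset, ...))
    out <- rbind(out, foci(fs))
  }
  out
}

# One-cell field helper used across detection and spatial tests.
singleCellField <- function(length = 3.2, width = 1, centre = c(3, 2)) {
  cl <- generateCell(length, width, centre = centre)
  list(cell = cl, set = methods::new("CellSet", cells = list(cl)))
}

# Exact closed-form ACF oracle for a frame-integrated telegraph process:
# the continuous process has correlation exp(-k |tau|); box-car averaging
# over frames of dt rescales all nonzero lags by a factor
# (cosh(k dt) - 1) / (k dt - 1 + exp(-k dt)), and the mean-subtracted
# 1/N-normalized sample ACF carries the standard first-order negative
# bias (S/N) (1 - rho), with S the correlation sum.
telegraphAcfOracle <- function(k, lags, dt, nFrames) {
  scale <- (cosh(k * dt) - 1) / (k * dt - 1 + exp(-k * dt))
  rho <- exp(-k * lags) * scale
  rho[lags == 0] <- 1
  S <- 1 + 2 * sum(exp(-k * dt * (1:1000)) * scale)
  rho - (S / nFrames) * (1 - rho)
}
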