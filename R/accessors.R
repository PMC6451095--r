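#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("cellId", "CellOutline", function(x, ...) x@cellId)

#' @rdname accessors
#' @export
setMethod("cellVertices", "CellOutline", function(x, ...) x@vertices)

#' @rdname accessors
#' @export
setMethod("cellLength", "CellOutline", function(x, ...) x@length)

#' @rdname accessors
#' @export
setMethod("cellWidth", "CellOutline", function(x, ...) x@width)

#' @rdname accessors
#' @export
setMethod("cellArea", "CellOutline", function(x, ...) x@area)

#' @rdname accessors
#' @export
setMethod("cellVolume", "CellOutline", function(x, ...) x@volume)

#' @rdname accessors
#' @export
setMethod("length", "CellSet", function(x) length(x@cells))

#' @rdname accessors
#' @param i index into a CellSet.
#' @export
setMethod("[[", "CellSet", function(x, i) x@cells[[i]])

#' @rdname accessors
#' @export
setMethod("cellTable", "CellSet", function(x, ...) {
  do.call(rbind, lapply(x@cells, function(cl) data.frame(
    cell_id = cl@cellId, time_point = cl@timePoint,
    length_um = cl@length, width_um = cl@width,
    area_um2 = cl@area, volume_fl = cl@volume,
    centre_x_um = cl@centre[1], centre_y_um = cl@centre[2],
    theta = cl@theta, stringsAsFactors = FALSE)))
})

#' @rdname accessors
#' @export
setMethod("foci", "FocusSet", function(x, ...) x@records)

#' @rdname accessors
#' @export
setMethod("foci", "SyntheticTimelapse", function(x, ...) x@foci@records)

#' @rdname accessors
#' @export
setMethod("length", "FocusSet", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("intensities", "TrajectorySet", function(x, ...) x@intensities)

#' @rdname accessors
#' @export
setMethod("frameTime", "TrajectorySet", function(x, ...) x@dt)

#' @rdname accessors
#' @export
setMethod("dim", "TrajectorySet", function(x) dim(x@intensities))

#' @rdname accessors
#' @export
setMethod("acfLags", "AcfCurve", function(x, ...) x@lags)

#' @rdname accessors
#' @export
setMethod("acfValues", "AcfCurve", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("acfSem", "AcfCurve", function(x, ...) x@sem)

#' @rdname accessors
#' @export
setMethod("amplitudes", "AcfDecomposition", function(x, ...)
  c(a_s = x@aS, a_m = x@aM, a_l = x@aL))

#' @rdname accessors
#' @export
setMethod("timescales", "AcfDecomposition", function(x, ...)
  c(tau_m = x@tauM, tau_l = x@tauL))

setMethod("show", "CellOutline", function(object) {
  cat(sprintf(
    "CellOutline '%s' (t = %g min): L = %.2f um, W = %.2f um, A = %.2f um^2, V = %.2f fL\n",
    object@cellId, object@timePoint, object@length, object@width,
    object@area, object@volume))
})

setMethod("show", "CellSet", function(object) {
  n <- length(object@cells)
  cat(sprintf("CellSet with %d cell outline%s\n", n, if (n == 1) "" else "s"))
  if (n) {
    tab <- cellTable(object)
    cat(sprintf("  mean length %.2f um, mean area %.2f um^2, time points: %s\n",
                mean(tab$length_um), mean(tab$area_um2),
                paste(sort(unique(tab$time_point)), collapse = ", ")))
  }
})

setMethod("show", "FocusSet", function(object) {
  r <- object@records
  cat(sprintf("FocusSet with %d foci (%d cell%s, channels: %s)\n",
              nrow(r), length(unique(r$cell_id)),
              if (length(unique(r$cell_id)) == 1) "" else "s",
              paste(sort(unique(as.character(r$channel))), collapse = ", ")))
})

setMethod("show", "TrajectorySet", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("TrajectorySet: %d %s trajectories x %d frames (dt = %g s)\n",
              d[2], object@origin, d[1], object@dt))
})

setMethod("show", "AcfCurve", function(object) {
  cat(sprintf(
    "AcfCurve: %d lags (0 to %.3f s), mean of %d trajector%s\n",
    length(object@lags), max(object@lags), object@nTrajectories,
    if (object@nTrajectories == 1) "y" else "ies"))
})

setMethod("show", "AcfDecomposition", function(object) {
  cat(sprintf("AcfDecomposition (%s model, fit from %.3f s):\n",
              object@model, object@fitStart))
  cat(sprintf("  a_s = %.3f, a_m = %.3f, a_l = %.3f\n",
              object@aS, object@aM, object@aL))
  cat(sprintf("  tau_m = %.3g s, tau_l = %.3g s\n", object@tauM, object@tauL))
})

setMethod("show", "SyntheticTimelapse", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SyntheticTimelapse: %d cells, %d fields, %d time points, channels %s\n",
    cfg@nCells, length(object@frames), length(object@cells),
    paste(cfg@channels, collapse = "/")))
})

setMethod("show", "TimelapseConfig", function(object) {
  cat(sprintf(
    "TimelapseConfig: %d cells, %g min x %g min interval, %d px frames @ %g um/px, seed %d\n",
    object@nCells, object@duration, object@interval, object@frameSizePx,
    object@pixelSize, object@seed))
  cat(sprintf("  channels: %s; focus density: %s foci/um^2\n",
              paste(object@channels, collapse = ", "),
              paste(sprintf("%s=%.2g", names(object@focusDensity),
                            object@focusDensity), collapse = ", ")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d mol/complex, k_on/k_off(complex) = %g/%g 1/s, k_on/k_off(molecule) = %g/%g 1/s\n",
    object@nMolPerComplex, object@kOnComplex, object@kOffComplex,
    object@kOnMolecule, object@kOffMolecule))
  cat(sprintf("  tau_bleach = %g s (%s clock), snr = %g, %d x %g s frames, seed %d\n",
              object@tauBleach, object@bleachClock, object@snr,
              object@nFrames, object@dt, object@seed))
})

setMethod("show", "WidthProfile", function(object) {
  cat(sprintf("WidthProfile: %d foci in %d bins of %.3g um\n",
              object@nFoci, length(object@mids), object@binWidth))
})

setMethod("show", "LinescanContour", function(object) {
  cat(sprintf("LinescanContour: %d time points x %d width bins (%.2f to %.2f um)\n",
              nrow(object@matrix), ncol(object@matrix),
              min(object@widthAxis), max(object@widthAxis)))
})
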