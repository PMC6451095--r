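#' @import methods
NULL

#' CellOutline: a rod-shaped bacterial cell outline
#'
#' Represents one segmented or generated cell as a closed polygon in image
#' coordinates (micrometres), together with derived geometric summaries.
#' Volumes use the spherocylinder model (cylinder of length \code{length -
#' width} capped by two hemispheres of diameter \code{width}), the standard
#' geometry for rod-shaped bacteria such as \emph{E. coli}.
#'
#' @slot cellId character scalar identifier.
#' @slot vertices two-column numeric matrix (x_um, y_um) of polygon vertices;
#'   the first vertex is repeated as the last row, so the ring is explicitly
#'   closed.
#' @slot length numeric, pole-to-pole length in um.
#' @slot width numeric, short-axis width in um.
#' @slot area numeric, area in um^2.
#' @slot volume numeric, spherocylinder volume in fL.
#' @slot timePoint numeric, minutes relative to the damage event.
#' @slot centre numeric length-2, (x, y) centre in um.
#' @slot theta numeric, orientation of the long axis in radians.
#'
#' @seealso [generateCell()], [segmentCells()]
#' @export
setClass("CellOutline", slots = c(
  cellId = "character",
  vertices = "matrix",
  length = "numeric",
  width = "numeric",
  area = "numeric",
  volume = "numeric",
  timePoint = "numeric",
  centre = "numeric",
  theta = "numeric"
))

setValidity("CellOutline", function(object) {
  msg <- character()
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 4L)
    msg <- c(msg, "vertices must be a numeric matrix with 2 columns and >= 4 rows")
  else if (any(abs(v[1L, ] - v[nrow(v), ]) > 1e-9))
    msg <- c(msg, "polygon must be closed (first vertex repeated as last)")
  if (!(object@length >= object@width) || !(object@width > 0))
    msg <- c(msg, "must satisfy length >= width > 0")
  if (!(object@area > 0)) msg <- c(msg, "area must be positive")
  if (!(object@volume > 0)) msg <- c(msg, "volume must be positive")
  if (length(msg)) msg else TRUE
})

#' CellSet: a collection of cell outlines
#'
#' Ordered list of [CellOutline-class] objects, usually all cells of one
#' field of view at one time point, or the full ground-truth cell table of a
#' synthetic time lapse.
#'
#' @slot cells list of \code{CellOutline}.
#' @export
setClass("CellSet", slots = c(cells = "list"))

setValidity("CellSet", function(object) {
  if (!all(vapply(object@cells, is, logical(1), "CellOutline")))
    return("all elements must be CellOutline objects")
  ids <- vapply(object@cells, function(x) x@cellId, character(1))
  tps <- vapply(object@cells, function(x) x@timePoint, numeric(1))
  if (anyDuplicated(paste(ids, tps)))
    return("cellId/timePoint combinations must be unique")
  TRUE
})

#' FocusSet: a table of detected or ground-truth foci
#'
#' Wraps a focus table with one row per focus. Mandatory columns:
#' \code{cell_id}, \code{channel}, \code{time_point}, \code{x_um},
#' \code{y_um}. Detected foci add \code{x_px}, \code{y_px},
#' \code{intensity} (background-subtracted integrated counts) and
#' \code{snr}; ground-truth and calibrated foci carry \code{n_molecules}.
#'
#' @slot records data.frame of focus records.
#' @slot pixelSize numeric, um per pixel (used for px/um conversions).
#' @export
setClass("FocusSet", slots = c(records = "data.frame", pixelSize = "numeric"))

setValidity("FocusSet", function(object) {
  need <- c("cell_id", "channel", "time_point", "x_um", "y_um")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    return(paste("missing focus columns:", paste(miss, collapse = ", ")))
  if (!(object@pixelSize > 0)) return("pixelSize must be positive")
  TRUE
})

#' TrajectorySet: intensity-versus-time traces on a fixed frame grid
#'
#' Column-per-trajectory matrix of focus intensities in units of the
#' single-molecule amplitude (simulated traces) or camera counts (traces
#' extracted from burst stacks). All trajectories share the frame interval
#' \code{dt}.
#'
#' @slot intensities numeric matrix, frames x trajectories.
#' @slot dt numeric, frame interval in seconds.
#' @slot origin character, \code{"measured"} or \code{"simulated"}.
#' @export
setClass("TrajectorySet", slots = c(
  intensities = "matrix", dt = "numeric", origin = "character"
))

setValidity("TrajectorySet", function(object) {
  if (!is.numeric(object@intensities) || !all(is.finite(object@intensities)))
    return("intensities must be a finite numeric matrix")
  if (!(object@dt > 0)) return("dt must be positive")
  if (!object@origin %in% c("measured", "simulated"))
    return("origin must be 'measured' or 'simulated'")
  TRUE
})

#' AcfCurve: a (mean) normalized autocorrelation function
#'
#' Normalization is mean-subtracted and variance-normalized, so the value at
#' lag zero is exactly one for a single trajectory. For ensemble means,
#' \code{sem} holds the per-lag standard error over trajectories.
#'
#' @slot lags numeric, lag times in seconds, starting at 0, strictly
#'   increasing in steps of dt.
#' @slot values numeric, correlation values.
#' @slot sem numeric, per-lag SEM (length 0 for single-trajectory curves).
#' @slot nTrajectories integer, number of trajectories averaged.
#' @export
setClass("AcfCurve", slots = c(
  lags = "numeric", values = "numeric", sem = "numeric",
  nTrajectories = "integer"
))

setValidity("AcfCurve", function(object) {
  if (length(object@lags) != length(object@values))
    return("lags and values must have equal length")
  if (object@lags[1] != 0 || any(diff(object@lags) <= 0))
    return("lags must start at 0 and be strictly increasing")
  if (length(object@sem) && length(object@sem) != length(object@values))
    return("sem must be empty or match values in length")
  TRUE
})

#' AcfDecomposition: short/medium/long decomposition of a mean ACF
#'
#' Decomposes a mean autocorrelation curve into a sub-frame (short)
#' amplitude \code{aS} plus one or two exponential components fitted beyond
#' the first lag: \code{aM * exp(-tau/tauM) + aL * exp(-tau/tauL)}.
#' Amplitudes close to one: \code{aS + aM + aL = 1}.
#'
#' @slot aS,aM,aL numeric amplitude fractions.
#' @slot tauM,tauL numeric timescales in seconds (tauM is NA for the
#'   single-exponential model).
#' @slot aSErr,aMErr,aLErr,tauMErr,tauLErr numeric uncertainties.
#' @slot model character: \code{"single"}, \code{"double"} or
#'   \code{"degenerate"} (no decay beyond lag zero).
#' @slot fitStart numeric, first lag (s) included in the exponential fit.
#' @export
setClass("AcfDecomposition", slots = c(
  aS = "numeric", aM = "numeric", aL = "numeric",
  tauM = "numeric", tauL = "numeric",
  aSErr = "numeric", aMErr = "numeric", aLErr = "numeric",
  tauMErr = "numeric", tauLErr = "numeric",
  model = "character", fitStart = "numeric"
))

setValidity("AcfDecomposition", function(object) {
  if (abs(object@aS + object@aM + object@aL - 1) > 1e-6)
    return("amplitudes must close to 1 (aS + aM + aL = 1)")
  if (object@model == "double" &&
      !(isTRUE(object@tauL > object@tauM)))
    return("double model requires tauL > tauM")
  TRUE
})

#' TimelapseConfig: parameters of the synthetic two-channel time lapse
#'
#' Defines the imaging geometry, kinetic schedule and camera model used by
#' [generateTimelapse()]. Defaults emulate burst/time-lapse imaging of
#' fluorescent fusion proteins in \emph{E. coli} growing in a flow cell:
#' snapshots every 10 min for 3 h, UV-like damage at t = 0, filamentation
#' from ~30 min, constant focus density as cells elongate and constant
#' copy-number concentration.
#'
#' Channel-dependent parameters (\code{focusDensity},
#' \code{stoichiometrySchedule}, \code{spatialMode}) are named per channel.
#' A stoichiometry schedule \code{list(before=1, after=2, switchTime=30)}
#' doubles molecules per focus from the switch time (dimerization); a
#' spatial schedule switches the placement mode (\code{"central"},
#' \code{"peripheral"}, \code{"uniform"}) the same way.
#'
#' @slot nCells integer, number of cells.
#' @slot pixelSize numeric, um per pixel (0.1).
#' @slot frameSizePx integer, square frame size in px (512).
#' @slot interval numeric, minutes between time points (10).
#' @slot duration numeric, total minutes (180).
#' @slot damageTime numeric, minutes of the damage event (0).
#' @slot filamentationOnset numeric, minutes after which cells start to
#'   elongate (30).
#' @slot growthRate numeric, specific elongation rate (1/min) of
#'   filamenting cells.
#' @slot staticFraction numeric, fraction of cells that never filament.
#' @slot focusDensity named numeric, foci per um^2 per channel.
#' @slot densityDecayRate numeric, exponential decay rate (1/min) applied to
#'   the focus density after the damage event (replication-shutdown preset).
#' @slot stoichiometrySchedule named list of per-channel schedules.
#' @slot spatialMode named list of per-channel spatial schedules.
#' @slot coPlacement numeric in [0, 1]: fraction of first-channel foci
#'   that receive a coincident partner focus in the second channel
#'   (30 nm placement jitter), for studying true colocalization against
#'   the chance baseline.
#' @slot copiesPerCell numeric, mean label copies per cell at t = 0.
#' @slot autofluorescenceEquiv numeric, cell autofluorescence expressed in
#'   molecule equivalents (2.5).
#' @slot unitIntensity numeric, integrated camera counts per molecule.
#' @slot psfSigmaPx numeric, PSF Gaussian sigma in px (1.3).
#' @slot snr numeric, single-molecule signal-to-noise (mean/sd of the
#'   integrated one-molecule signal; the photon scale is snr^2).
#' @slot offset numeric, camera offset counts.
#' @slot readNoiseSd numeric, Gaussian read noise sd in counts.
#' @slot seed integer, master seed; identical configs give identical output.
#' @slot channels character, channel names.
#' @export
setClass("TimelapseConfig", slots = c(
  nCells = "integer", pixelSize = "numeric", frameSizePx = "integer",
  interval = "numeric", duration = "numeric", damageTime = "numeric",
  filamentationOnset = "numeric", growthRate = "numeric",
  staticFraction = "numeric", focusDensity = "numeric",
  densityDecayRate = "numeric", stoichiometrySchedule = "list",
  spatialMode = "list", coPlacement = "numeric",
  copiesPerCell = "numeric",
  autofluorescenceEquiv = "numeric", unitIntensity = "numeric",
  psfSigmaPx = "numeric", snr = "numeric", offset = "numeric",
  readNoiseSd = "numeric", seed = "integer", channels = "character"
))

setValidity("TimelapseConfig", function(object) {
  msg <- character()
  nonneg <- c(growthRate = object@growthRate,
              staticFraction = object@staticFraction,
              densityDecayRate = object@densityDecayRate,
              copiesPerCell = object@copiesPerCell,
              autofluorescenceEquiv = object@autofluorescenceEquiv,
              readNoiseSd = object@readNoiseSd, offset = object@offset)
  if (any(nonneg < 0))
    msg <- c(msg, paste("negative parameter:",
                        paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  if (any(object@focusDensity < 0)) msg <- c(msg, "focusDensity must be >= 0")
  if (!(object@pixelSize > 0)) msg <- c(msg, "pixelSize must be > 0")
  if (!(object@unitIntensity > 0)) msg <- c(msg, "unitIntensity must be > 0")
  if (!(object@snr > 0)) msg <- c(msg, "snr must be > 0")
  if (object@duration < object@interval)
    msg <- c(msg, "duration must be >= interval")
  if (object@coPlacement < 0 || object@coPlacement > 1)
    msg <- c(msg, "coPlacement must be in [0, 1]")
  if (!all(object@channels %in% names(object@focusDensity)))
    msg <- c(msg, "focusDensity must be named for every channel")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the stochastic trajectory simulator
#'
#' Parameters of the three-stage intensity-trajectory simulator: a complex
#' binds/unbinds DNA (telegraph kinetics \code{kOnComplex}/\code{kOffComplex}),
#' individual labelled molecules exchange on the complex
#' (\code{kOnMolecule}/\code{kOffMolecule}), and each molecule photobleaches
#' with mean emitting lifetime \code{tauBleach}. A molecule produces signal
#' only while it is on the complex, the complex is on DNA and the molecule
#' is unbleached.
#'
#' @slot nMolPerComplex integer >= 1, maximum molecules per complex.
#' @slot kOnComplex,kOffComplex numeric rates (1/s) for DNA binding.
#' @slot kOnMolecule,kOffMolecule numeric rates (1/s) for molecule exchange.
#' @slot tauBleach numeric, mean photobleaching time (s).
#' @slot snr numeric, single-molecule per-frame mean/sd.
#' @slot nFrames integer, frames per trajectory (300).
#' @slot dt numeric, frame time (0.034 s).
#' @slot bleachClock character, \code{"illumination"} (bleaching clock runs
#'   only while emitting) or \code{"wall"} (runs always).
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig", slots = c(
  nMolPerComplex = "integer",
  kOnComplex = "numeric", kOffComplex = "numeric",
  kOnMolecule = "numeric", kOffMolecule = "numeric",
  tauBleach = "numeric", snr = "numeric",
  nFrames = "integer", dt = "numeric",
  bleachClock = "character", seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nMolPerComplex < 1L) msg <- c(msg, "nMolPerComplex must be >= 1")
  rates <- c(object@kOnComplex, object@kOffComplex,
             object@kOnMolecule, object@kOffMolecule)
  if (any(rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (!(object@tauBleach > 0)) msg <- c(msg, "tauBleach must be > 0")
  if (!(object@dt > 0)) msg <- c(msg, "dt must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (!object@bleachClock %in% c("illumination", "wall"))
    msg <- c(msg, "bleachClock must be 'illumination' or 'wall'")
  if (length(msg)) msg else TRUE
})

#' SyntheticTimelapse: rendered stacks plus ground truth
#'
#' Result of [generateTimelapse()]: rendered image frames per field, time
#' point and channel, together with the ground-truth cell outlines and focus
#' placements that produced them.
#'
#' @slot frames nested list: \code{frames[[field]][[time]][[channel]]} is a
#'   numeric matrix of camera counts.
#' @slot cells list over time points of [CellSet-class].
#' @slot foci [FocusSet-class] of ground-truth foci (all time points).
#' @slot cellTable data.frame of per-cell, per-time ground truth (lengths,
#'   copies, field assignment).
#' @slot config the [TimelapseConfig-class] used.
#' @export
setClass("SyntheticTimelapse", slots = c(
  frames = "list", cells = "list", foci = "FocusSet",
  cellTable = "data.frame", config = "TimelapseConfig"
))

#' WidthProfile: histogram of focus positions across the cell width
#'
#' Signed short-axis coordinates binned symmetrically about the centre
#' spline (0 um); for a 1-um wide cell the membrane sits at +/- 0.5 um.
#'
#' @slot mids numeric bin midpoints (um).
#' @slot counts integer counts per bin.
#' @slot binWidth numeric (um).
#' @slot nFoci integer, total foci binned.
#' @export
setClass("WidthProfile", slots = c(
  mids = "numeric", counts = "integer", binWidth = "numeric",
  nFoci = "integer"
))

setValidity("WidthProfile", function(object) {
  if (length(object@mids) != length(object@counts))
    return("mids and counts must match in length")
  if (sum(object@counts) != object@nFoci)
    return("histogram counts must sum to nFoci")
  TRUE
})

#' LinescanContour: time x width matrix of mean enhanced intensity
#'
#' Average focus-enhanced fluorescence across the cell short axis, one row
#' per time point, used to visualize central versus membrane-proximal
#' localization over a damage response.
#'
#' @slot matrix numeric matrix, time points x width bins.
#' @slot widthAxis numeric, signed width positions (um).
#' @slot timeAxis numeric, time points (min).
#' @export
setClass("LinescanContour", slots = c(
  matrix = "matrix", widthAxis = "numeric", timeAxis = "numeric"
))

setValidity("LinescanContour", function(object) {
  if (nrow(object@matrix) != length(object@timeAxis) ||
      ncol(object@matrix) != length(object@widthAxis))
    return("matrix dimensions must match time and width axes")
  if (is.unsorted(object@widthAxis) || is.unsorted(object@timeAxis))
    return("axes must be monotone increasing")
  TRUE
})
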