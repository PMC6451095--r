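#' Flat-field correction
#'
#' Divides an image pixelwise by an illumination profile normalized to unit
#' maximum, correcting for excitation-beam inhomogeneity (e.g. a centre
#' ~12 percent brighter than the corners).
#'
#' @param image 2D matrix of counts (offset already subtracted).
#' @param profile 2D matrix of the same shape, strictly positive.
#' @return corrected matrix.
#' @examples
#' img <- matrix(100, 8, 8)
#' flattenField(img, matrix(1, 8, 8))  # unchanged
#' @export
flattenField <- function(image, profile) {
  stopIfNot(all(dim(image) == dim(profile)),
            "profile must have the same shape as the image")
  stopIfNot(all(profile > 0), "illumination profile must be strictly positive")
  image / (profile / max(profile))
}

#' Radial illumination profile
#'
#' Convenience generator of a smooth radial beam profile with a given
#' centre-to-corner intensity ratio, for synthetic flat-fielding tests.
#'
#' @param n frame side in px.
#' @param centreCornerRatio centre/corner intensity ratio (default 1.12).
#' @return n x n matrix with maximum 1 at the centre.
#' @export
illuminationProfile <- function(n, centreCornerRatio = 1.12) {
  ctr <- (n + 1) / 2
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+")
  prof <- 1 - (1 - 1 / centreCornerRatio) * r2 / max(r2)
  prof / max(prof)
}

# Change points of a piecewise-constant signal by binary segmentation:
# recursively split at the maximal reduction in residual sum of squares,
# accepting a split when the level change exceeds `nSigma` times the
# robust frame-to-frame noise.
findChangePoints <- function(x, nSigma = 3, minSeg = 3L) {
  # exact-zero differences (e.g. fully bleached, shot-noise-free frames)
  # carry no noise information and would collapse the MAD
  dx <- diff(x)
  dx <- dx[dx != 0]
  noise <- if (length(dx)) stats::mad(dx) / sqrt(2) else 0
  noise <- max(noise, 1e-9 * max(abs(x), 1))
  splits <- integer(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * minSeg) return()
    seg <- x[lo:hi]
    cs <- cumsum(seg); tot <- cs[n]
    ks <- minSeg:(n - minSeg)
    # RSS reduction of splitting after position k
    gain <- (cs[ks] - ks * tot / n)^2 * n / (ks * (n - ks))
    k <- ks[which.max(gain)]
    mu1 <- cs[k] / k; mu2 <- (tot - cs[k]) / (n - k)
    sePool <- noise * sqrt(1 / k + 1 / (n - k))
    if (abs(mu1 - mu2) <= nSigma * sePool) return()
    splits[length(splits) + 1L] <<- lo + k - 1L  # last index of left part
    recurse(lo, lo + k - 1L)
    recurse(lo + k, hi)
  }
  recurse(1L, length(x))
  sort(splits)
}

#' Calibrate the single-molecule intensity unit from bleaching steps
#'
#' Finds discrete steps in burst-acquisition focus trajectories by
#' change-point detection and summarizes the distribution of step
#' magnitudes (downward photobleaching steps and upward single-molecule
#' return events alike). The unit intensity is the mean of the dominant
#' mode of the magnitude distribution, which rejects occasional
#' double-molecule steps.
#'
#' @param trajectories a [TrajectorySet-class] or numeric matrix
#'   (frames x trajectories) of focus intensities in counts.
#' @param nSigma change-point acceptance threshold in noise sigmas.
#' @param minTrajectories minimum trajectories that must contain steps.
#' @return list with \code{unit} (counts/molecule), \code{se},
#'   \code{nSteps}, \code{cv} and the vector of accepted step magnitudes.
#' @export
unitIntensityFromSteps <- function(trajectories, nSigma = 3,
                                   minTrajectories = 10L) {
  m <- if (is(trajectories, "TrajectorySet")) intensities(trajectories)
       else as.matrix(trajectories)
  steps <- numeric(0)
  nWithSteps <- 0L
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    cp <- findChangePoints(x, nSigma = nSigma)
    if (!length(cp)) next
    nWithSteps <- nWithSteps + 1L
    bounds <- c(0L, cp, length(x))
    lev <- vapply(seq_len(length(bounds) - 1L), function(s)
      mean(x[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
    steps <- c(steps, abs(diff(lev)))
  }
  stopIfNot(length(steps) > 0 && nWithSteps >= minTrajectories,
            sprintf(paste("calibration failed: %d trajectories with steps",
                          "(need >= %d) - check that trajectories contain",
                          "discrete bleaching steps"),
                    nWithSteps, minTrajectories))
  # dominant mode of the magnitude distribution
  if (length(steps) >= 5 && stats::sd(steps) > 0) {
    d <- tryCatch(stats::density(steps, bw = "SJ-ste", n = 512),
                  error = function(e) stats::density(steps, n = 512))
    peak <- d$x[which.max(d$y)]
  } else peak <- stats::median(steps)
  core <- steps[steps > 0.55 * peak & steps < 1.45 * peak]
  if (length(core) < 3) core <- steps
  unit <- mean(core)
  list(unit = unit, se = stats::sd(core) / sqrt(length(core)),
       nSteps = length(steps), cv = stats::sd(core) / unit,
       steps = steps)
}

#' Copy-number estimate for one cell
#'
#' Converts a cell's integrated fluorescence to a molecule count:
#' \code{n = max(0, mean_intensity * area_px / unit - autofluorescence)}.
#' The autofluorescence correction is a population constant expressed in
#' molecule equivalents. Negative corrected counts clamp to zero with a
#' warning (dim cells below the autofluorescence floor).
#'
#' @param meanCellIntensity offset-subtracted mean counts per pixel.
#' @param areaPx cell area in pixels.
#' @param unitIntensity counts per molecule (> 0).
#' @param autofluorescenceEquiv autofluorescence in molecule equivalents.
#' @param volumeFl optional cell volume (fL) to add a concentration.
#' @param cellId identifier.
#' @return one-row data.frame: cell_id, integrated_signal, n_molecules,
#'   volume_fl, concentration_nM.
#' @examples
#' # integrated signal worth 20.6 molecule units -> 18.1 molecules
#' copyNumber(20.6, 100, unitIntensity = 100,
#'            autofluorescenceEquiv = 2.5)$n_molecules
#' @export
copyNumber <- function(meanCellIntensity, areaPx, unitIntensity,
                       autofluorescenceEquiv = 2.5, volumeFl = NA_real_,
                       cellId = "cell_1") {
  stopIfNot(is.numeric(unitIntensity) && unitIntensity > 0,
            "unitIntensity must be > 0")
  integrated <- meanCellIntensity * areaPx
  n <- integrated / unitIntensity - autofluorescenceEquiv
  if (n < 0) {
    warning("corrected copy number negative; clamped to 0", call. = FALSE)
    n <- 0
  }
  conc <- if (is.finite(volumeFl)) moleculeConcentration(n, volumeFl)
          else NA_real_
  data.frame(cell_id = cellId, integrated_signal = integrated,
             n_molecules = n, volume_fl = volumeFl,
             concentration_nM = conc, stringsAsFactors = FALSE)
}

#' Molecule count to concentration
#'
#' \code{C = n / (V * N_A)} reported in nanomolar; one molecule in 1.66 fL
#' is 1 nM.
#'
#' @param nMolecules molecule count (>= 0).
#' @param volumeFl cell volume in fL (> 0).
#' @return concentration in nM.
#' @export
moleculeConcentration <- function(nMolecules, volumeFl) {
  stopIfNot(all(volumeFl > 0), "volume must be > 0")
  avogadro <- 6.02214076e23
  nMolecules / (volumeFl * 1e-15 * avogadro) * 1e9
}

#' Molecules per focus
#'
#' Ratio of a focus's background-subtracted integrated intensity to the
#' single-molecule unit, with its nearest-integer assignment.
#'
#' @param focusIntensity integrated intensities (counts, >= 0).
#' @param unitIntensity counts per molecule (> 0).
#' @return data.frame with \code{ratio} and \code{n_molecules}.
#' @export
moleculesPerFocus <- function(focusIntensity, unitIntensity) {
  stopIfNot(unitIntensity > 0, "unitIntensity must be > 0")
  stopIfNot(all(focusIntensity >= 0), "focus intensities must be >= 0")
  ratio <- focusIntensity / unitIntensity
  data.frame(ratio = ratio, n_molecules = as.integer(round(ratio)))
}

#' Fraction of labelled molecules bound to DNA
#'
#' \code{100 * fociPerCell * moleculesPerFocus / copiesPerCell} percent:
#' with 2 foci of one molecule among 18 copies, ~11 percent of molecules
#' are bound; dimeric foci double this to ~22 percent.
#'
#' @param fociPerCell mean foci per cell.
#' @param moleculesPerFocus molecules per focus.
#' @param copiesPerCell labelled copies per cell (> 0).
#' @return percentage (0-100 under normal inputs).
#' @examples
#' boundFraction(2, 1, 18)  # 11.1
#' boundFraction(2, 2, 18)  # 22.2
#' @export
boundFraction <- function(fociPerCell, moleculesPerFocus, copiesPerCell) {
  stopIfNot(copiesPerCell > 0, "copiesPerCell must be > 0")
  100 * fociPerCell * moleculesPerFocus / copiesPerCell
}

#' Estimate copy numbers for every cell in a frame
#'
#' Applies [copyNumber()] across a field: per cell, the offset-subtracted
#' mean intensity of the (first) frame times the cell area in pixels gives
#' the integrated signal, divided by the single-molecule unit and corrected
#' for autofluorescence. The camera offset defaults to the median off-cell
#' intensity.
#'
#' @param image 2D matrix (the first burst frame).
#' @param cells a [CellSet-class].
#' @param unitIntensity counts per molecule.
#' @param autofluorescenceEquiv molecule equivalents.
#' @param offset camera offset; estimated off-cell when NULL.
#' @param pixelSize um per pixel.
#' @return data.frame, one row per cell, as in [copyNumber()].
#' @export
estimateCopyNumbers <- function(image, cells, unitIntensity,
                                autofluorescenceEquiv = 2.5, offset = NULL,
                                pixelSize = 0.1) {
  stopifnot(is(cells, "CellSet"))
  stats <- perCellStats(methods::new("FocusSet", records = data.frame(
    cell_id = character(0), channel = character(0),
    time_point = numeric(0), x_um = numeric(0), y_um = numeric(0)),
    pixelSize = pixelSize), cells, image = image, offset = offset,
    pixelSize = pixelSize)$perCell
  areaPx <- stats$area_um2 / pixelSize^2
  out <- do.call(rbind, lapply(seq_len(nrow(stats)), function(k)
    copyNumber(stats$mean_cell_intensity[k], areaPx[k], unitIntensity,
               autofluorescenceEquiv, volumeFl = stats$volume_fl[k],
               cellId = stats$cell_id[k])))
  out
}
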