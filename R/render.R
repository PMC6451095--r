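#' Render one fluorescence frame from cells and foci
#'
#' Renders a synthetic wide-field fluorescence frame. Each DNA-bound focus
#' is drawn as a 2D Gaussian spot of fixed PSF sigma whose integrated
#' (background-subtracted) intensity is \code{n_molecules * unitIntensity}.
#' Freely diffusing molecules blur out at 34-100 ms exposures, so unbound
#' copies and cellular autofluorescence contribute a uniform per-cell
#' background instead of discrete emitters. The camera model is Poisson
#' shot noise (scaled so a one-molecule focus has integrated mean/sd =
#' \code{snr}) plus Gaussian read noise plus a constant offset.
#'
#' @param cells a [CellSet-class] (all cells of the field).
#' @param fociTable data.frame of foci (columns x_um, y_um, n_molecules,
#'   cell_id); every focus must lie inside some cell polygon.
#' @param frameSizePx frame side in pixels.
#' @param pixelSize um per pixel.
#' @param psfSigmaPx Gaussian PSF sigma in pixels.
#' @param unitIntensity integrated counts per molecule.
#' @param freeCopies numeric vector of unbound label copies per cell (same
#'   order as \code{cells}); spread uniformly within each outline.
#' @param autofluorescenceEquiv per-cell autofluorescence in molecule
#'   equivalents, also spread uniformly.
#' @param snr single-molecule integrated signal-to-noise; the photon gain is
#'   \code{snr^2 / unitIntensity} photons per count.
#' @param offset camera offset in counts.
#' @param readNoiseSd Gaussian read noise sd in counts.
#' @param noise logical; \code{FALSE} returns the noise-free expectation
#'   (offset included).
#' @param seed optional integer seed.
#' @return numeric matrix (\code{frameSizePx x frameSizePx}) of counts.
#' @examples
#' cl <- generateCell(3, 1, centre = c(3, 2))
#' cs <- new("CellSet", cells = list(cl))
#' f <- placeFoci(cl, 2, "uniform", seed = 1)
#' img <- renderFrame(cs, f, frameSizePx = 64L, seed = 1)
#' @export
renderFrame <- function(cells, fociTable, frameSizePx = 512L,
                        pixelSize = 0.1, psfSigmaPx = 1.3,
                        unitIntensity = 100, freeCopies = 0,
                        autofluorescenceEquiv = 2.5, snr = 30,
                        offset = 100, readNoiseSd = 1, noise = TRUE,
                        seed = NULL) {
  stopifnot(is(cells, "CellSet"))
  n <- as.integer(frameSizePx)
  img <- matrix(0, n, n)
  nc <- length(cells)
  freeCopies <- rep_len(freeCopies, nc)

  if (nrow(fociTable)) {
    # tolerance of 20 nm absorbs the chord-versus-arc error of the
    # discretized cap polygons
    tol <- 0.02
    inside <- rep(FALSE, nrow(fociTable))
    for (k in seq_len(nc)) {
      idx <- which(!inside)
      if (!length(idx)) break
      v <- cells[[k]]@vertices
      hit <- rep(FALSE, length(idx))
      for (sh in list(c(0, 0), c(tol, 0), c(-tol, 0), c(0, tol),
                      c(0, -tol)))
        hit <- hit | pointsInPolygon(v, fociTable$x_um[idx] + sh[1],
                                     fociTable$y_um[idx] + sh[2])
      inside[idx] <- hit
    }
    stopIfNot(all(inside), "every focus must lie inside a cell outline")
  }

  # diffuse per-cell background: free copies + autofluorescence
  for (k in seq_len(nc)) {
    px <- pixelsInsideCell(cells[[k]], dim(img), pixelSize)
    if (!length(px)) next
    tot <- (freeCopies[k] + autofluorescenceEquiv) * unitIntensity
    img[px] <- img[px] + tot / length(px)
  }

  # Gaussian spots
  if (nrow(fociTable)) {
    half <- ceiling(5 * psfSigmaPx)
    for (k in seq_len(nrow(fociTable))) {
      x0 <- fociTable$x_um[k] / pixelSize  # fractional px, centre at j - 0.5
      y0 <- fociTable$y_um[k] / pixelSize
      nm <- if ("n_molecules" %in% names(fociTable))
        fociTable$n_molecules[k] else 1
      amp <- nm * unitIntensity / (2 * pi * psfSigmaPx^2)
      j0 <- round(x0 + 0.5); i0 <- round(y0 + 0.5)
      js <- max(1L, j0 - half):min(n, j0 + half)
      is <- max(1L, i0 - half):min(n, i0 + half)
      gx <- exp(-((js - 0.5) - x0)^2 / (2 * psfSigmaPx^2))
      gy <- exp(-((is - 0.5) - y0)^2 / (2 * psfSigmaPx^2))
      img[is, js] <- img[is, js] + amp * outer(gy, gx)
    }
  }

  if (!noise) return(img + offset)
  withSeed(seed, {
    gain <- snr^2 / unitIntensity   # photons per count
    shot <- matrix(stats::rpois(n * n, img * gain) / gain, n, n)
    shot + offset + matrix(stats::rnorm(n * n, 0, readNoiseSd), n, n)
  })
}

#' Construct a synthetic time-lapse configuration
#'
#' Builds a validated [TimelapseConfig-class]. Defaults encode the study
#' conditions emulated by the generator: 100-nm pixels on a 512 px frame,
#' one two-channel snapshot every 10 min for 3 h with a damage event at
#' t = 0, filamentation starting ~30 min later, a channel-A focus density
#' tuned to ~2.2 foci per ~2.8 um^2 cell with monomer-to-dimer switching at
#' 30 min, a sparse central-then-peripheral channel B, 18 label copies per
#' cell, autofluorescence worth 2.5 molecules, and 100 counts per molecule.
#'
#' @param nCells number of cells.
#' @param pixelSize um per px.
#' @param frameSizePx frame side (px).
#' @param interval,duration,damageTime,filamentationOnset minutes.
#' @param growthRate specific elongation rate (1/min) after onset.
#' @param staticFraction fraction of cells that never filament.
#' @param focusDensity named per-channel density (foci/um^2).
#' @param densityDecayRate exponential decay (1/min) of focus density after
#'   the damage event; nonzero in the replication-shutdown preset.
#' @param stoichiometrySchedule named list of
#'   \code{list(before, after, switchTime)} per channel.
#' @param spatialMode named list of \code{list(before, after, switchTime)}
#'   per channel with placement modes.
#' @param coPlacement fraction of first-channel foci given a coincident
#'   second-channel partner (30 nm jitter).
#' @param copiesPerCell mean label copies per cell at t = 0.
#' @param autofluorescenceEquiv molecule equivalents.
#' @param unitIntensity counts per molecule.
#' @param psfSigmaPx PSF sigma (px).
#' @param snr single-molecule integrated signal-to-noise.
#' @param offset,readNoiseSd camera model (counts).
#' @param seed master seed.
#' @param channels channel names.
#' @return a [TimelapseConfig-class].
#' @export
timelapseConfig <- function(nCells = 100L, pixelSize = 0.1,
                            frameSizePx = 512L, interval = 10,
                            duration = 180, damageTime = 0,
                            filamentationOnset = 30, growthRate = 0.017,
                            staticFraction = 0,
                            focusDensity = c(A = 0.79, B = 0.15),
                            densityDecayRate = 0,
                            stoichiometrySchedule = list(
                              A = list(before = 1L, after = 2L, switchTime = 30),
                              B = list(before = 1L, after = 1L, switchTime = Inf)),
                            spatialMode = list(
                              A = list(before = "central", after = "central",
                                       switchTime = Inf),
                              B = list(before = "central", after = "peripheral",
                                       switchTime = 30)),
                            coPlacement = 0,
                            copiesPerCell = 18,
                            autofluorescenceEquiv = 2.5,
                            unitIntensity = 100, psfSigmaPx = 1.3,
                            snr = 30, offset = 100, readNoiseSd = 1,
                            seed = 1L, channels = c("A", "B")) {
  methods::new("TimelapseConfig", nCells = as.integer(nCells),
               pixelSize = pixelSize, frameSizePx = as.integer(frameSizePx),
               interval = interval, duration = duration,
               damageTime = damageTime,
               filamentationOnset = filamentationOnset,
               growthRate = growthRate, staticFraction = staticFraction,
               focusDensity = focusDensity,
               densityDecayRate = densityDecayRate,
               stoichiometrySchedule = stoichiometrySchedule,
               spatialMode = spatialMode, coPlacement = coPlacement,
               copiesPerCell = copiesPerCell,
               autofluorescenceEquiv = autofluorescenceEquiv,
               unitIntensity = unitIntensity, psfSigmaPx = psfSigmaPx,
               snr = snr, offset = offset, readNoiseSd = readNoiseSd,
               seed = as.integer(seed), channels = channels)
}

#' Named generator presets
#'
#' \code{"replicationShutdown"} emulates a temperature-sensitive helicase
#' scenario: after the damage event the focus density decays exponentially
#' (replication forks are lost, and with them the binding sites), instead
#' of staying constant. \code{"staticMutant"} emulates a damage-signalling
#' mutant in which most cells (90 percent) never filament.
#'
#' @param name preset name.
#' @param ... overrides passed on to [timelapseConfig()].
#' @return a [TimelapseConfig-class].
#' @export
timelapsePreset <- function(name = c("replicationShutdown", "staticMutant"),
                            ...) {
  name <- match.arg(name)
  args <- list(...)
  base <- switch(name,
    replicationShutdown = list(densityDecayRate = 0.025),
    staticMutant = list(staticFraction = 0.9))
  do.call(timelapseConfig, utils::modifyList(base, args))
}

# schedule value at time t
scheduleAt <- function(sched, t)
  if (t >= sched$switchTime) sched$after else sched$before

# lay cells out in horizontal lanes across one or more fields
layoutCells <- function(config) {
  fovUm <- config@frameSizePx * config@pixelSize
  lanePitch <- 2.5
  lanes <- max(1L, floor((fovUm - 2) / lanePitch))
  nFields <- ceiling(config@nCells / lanes)
  withSeed(childSeed(config@seed, 1), {
    widths <- pmax(0.8, stats::rnorm(config@nCells, 1, 0.05))
    len0 <- pmax(widths + 0.2, stats::rnorm(config@nCells, 3, 0.4))
    static <- stats::runif(config@nCells) < config@staticFraction
    xJit <- stats::runif(config@nCells, -3, 3)
    data.frame(
      cell_id = sprintf("cell_%03d", seq_len(config@nCells)),
      field = rep(seq_len(nFields), each = lanes)[seq_len(config@nCells)],
      lane = rep(seq_len(lanes), nFields)[seq_len(config@nCells)],
      x0 = fovUm / 2 + xJit, y0 = NA_real_,
      width = widths, length0 = len0, static = static,
      stringsAsFactors = FALSE)
  }) -> tab
  tab$y0 <- 1.5 + (tab$lane - 1) * lanePitch
  tab$maxLength <- fovUm - 2
  tab
}

cellLengthAt <- function(len0, t, config, static) {
  if (static || t <= config@filamentationOnset) return(len0)
  min(len0 * exp(config@growthRate * (t - config@filamentationOnset)),
      45)
}

#' Generate a ground-truthed two-channel synthetic time lapse
#'
#' Simulates the full imaging experiment: rod-shaped cells that elongate
#' exponentially after the filamentation onset, ground-truth foci placed at
#' constant focus density (counts proportional to cell area), per-channel
#' stoichiometry and spatial-mode schedules, copy numbers that scale with
#' cell volume (constant concentration, hence constant mean cell
#' intensity), and rendered camera frames for every field, time point and
#' channel. Identical configurations (including the seed) produce
#' bit-identical stacks and tables.
#'
#' @param config a [TimelapseConfig-class].
#' @param render logical; \code{FALSE} skips frame rendering and returns
#'   ground truth only (fast path for statistical tests).
#' @return a [SyntheticTimelapse-class].
#' @export
generateTimelapse <- function(config, render = TRUE) {
  stopifnot(is(config, "TimelapseConfig"))
  methods::validObject(config)
  tps <- seq(0, config@duration, by = config@interval)
  layout <- layoutCells(config)
  nFields <- max(layout$field)
  fovUm <- config@frameSizePx * config@pixelSize

  cellsByTp <- vector("list", length(tps))
  fociList <- list()
  rowsList <- list()
  vol0 <- spherocylinderVolume(layout$length0, layout$width)
  meanVol0 <- mean(vol0)

  for (ti in seq_along(tps)) {
    t <- tps[ti]
    cl <- vector("list", nrow(layout))
    for (k in seq_len(nrow(layout))) {
      L <- cellLengthAt(layout$length0[k], t, config, layout$static[k])
      cl[[k]] <- generateCell(L, layout$width[k],
                              cellId = layout$cell_id[k],
                              centre = c(layout$x0[k], layout$y0[k]),
                              theta = 0, timePoint = t)
    }
    cellsByTp[[ti]] <- methods::new("CellSet", cells = cl)

    for (k in seq_len(nrow(layout))) {
      cell <- cl[[k]]
      copies <- config@copiesPerCell * cell@volume / meanVol0
      boundTot <- 0
      for (ch in config@channels) {
        dens <- config@focusDensity[[ch]]
        if (config@densityDecayRate > 0 && t > config@damageTime)
          dens <- dens * exp(-config@densityDecayRate * (t - config@damageTime))
        sto <- scheduleAt(config@stoichiometrySchedule[[ch]], t)
        mode <- scheduleAt(config@spatialMode[[ch]], t)
        sd1 <- childSeed(config@seed, 2, ti, k, match(ch, config@channels))
        nf <- withSeed(sd1, stats::rpois(1, dens * cell@area))
        if (nf > 0) {
          f <- placeFoci(cell, nf, mode = mode, stoichiometry = sto,
                         channel = ch, seed = childSeed(sd1, 3))
          fociList[[length(fociList) + 1L]] <- f
          if (ch == config@channels[1]) {
            boundTot <- boundTot + sum(f$n_molecules)
            if (config@coPlacement > 0 && length(config@channels) >= 2) {
              sd2 <- childSeed(config@seed, 5, ti, k)
              fB <- withSeed(sd2, {
                pick <- stats::runif(nrow(f)) < config@coPlacement
                if (any(pick)) {
                  g <- f[pick, , drop = FALSE]
                  g$channel <- config@channels[2]
                  g$x_um <- g$x_um + stats::rnorm(nrow(g), 0, 0.03)
                  g$y_um <- g$y_um + stats::rnorm(nrow(g), 0, 0.03)
                  g$n_molecules <- 1L
                  # keep jittered partners inside the cell
                  keep <- pointsInPolygon(cell@vertices, g$x_um, g$y_um)
                  g[keep, , drop = FALSE]
                } else NULL
              })
              if (!is.null(fB) && nrow(fB))
                fociList[[length(fociList) + 1L]] <- fB
            }
          }
        }
      }
      rowsList[[length(rowsList) + 1L]] <- data.frame(
        cell_id = cell@cellId, time_point = t, field = layout$field[k],
        length_um = cell@length, width_um = cell@width,
        area_um2 = cell@area, volume_fl = cell@volume,
        copies = copies, bound = boundTot, static = layout$static[k],
        stringsAsFactors = FALSE)
    }
  }

  fociTab <- if (length(fociList)) do.call(rbind, fociList) else
    placeFoci(generateCell(2, 1), 0L)
  cellTab <- do.call(rbind, rowsList)

  frames <- vector("list", nFields)
  if (render) {
    for (fd in seq_len(nFields)) {
      inField <- layout$cell_id[layout$field == fd]
      frames[[fd]] <- vector("list", length(tps))
      for (ti in seq_along(tps)) {
        t <- tps[ti]
        cset <- methods::new("CellSet",
          cells = Filter(function(x) x@cellId %in% inField,
                         cellsByTp[[ti]]@cells))
        perCh <- list()
        for (ch in config@channels) {
          ft <- fociTab[fociTab$time_point == t & fociTab$channel == ch &
                          fociTab$cell_id %in% inField, , drop = FALSE]
          rows <- cellTab[cellTab$time_point == t &
                            cellTab$cell_id %in% inField, ]
          rows <- rows[match(vapply(cset@cells, cellId, character(1)),
                             rows$cell_id), ]
          boundPerCell <- vapply(rows$cell_id, function(id)
            sum(ft$n_molecules[ft$cell_id == id]), numeric(1))
          free <- pmax(0, rows$copies - boundPerCell)
          perCh[[ch]] <- renderFrame(
            cset, ft, frameSizePx = config@frameSizePx,
            pixelSize = config@pixelSize, psfSigmaPx = config@psfSigmaPx,
            unitIntensity = config@unitIntensity, freeCopies = free,
            autofluorescenceEquiv = config@autofluorescenceEquiv,
            snr = config@snr, offset = config@offset,
            readNoiseSd = config@readNoiseSd,
            seed = childSeed(config@seed, 4, fd, ti,
                             match(ch, config@channels)))
        }
        frames[[fd]][[ti]] <- perCh
      }
      names(frames[[fd]]) <- paste0("t", tps)
    }
  }

  methods::new("SyntheticTimelapse", frames = frames, cells = cellsByTp,
               foci = methods::new("FocusSet", records = fociTab,
                                   pixelSize = config@pixelSize),
               cellTable = cellTab, config = config)
}

#' Render a photobleaching burst stack for one field of cells
#'
#' Renders a continuous-excitation burst acquisition: foci keep their
#' positions while their constituent molecules photobleach stochastically
#' (exponential emitting lifetime \code{tauBleach}), and the diffuse
#' unbound pool bleaches with the same time constant. The first frame
#' matches the time-lapse intensity model, so copy numbers estimated from
#' frame one are directly comparable; later frames show the stepwise focus
#' intensity loss used for single-molecule intensity calibration.
#'
#' @param cells a [CellSet-class].
#' @param fociTable ground-truth foci for these cells (one time point).
#' @param copies numeric vector of total label copies per cell.
#' @param nFrames number of frames.
#' @param dt frame time (s).
#' @param tauBleach mean emitting lifetime (s).
#' @param config a [TimelapseConfig-class] supplying the camera model.
#' @param seed integer seed.
#' @return list with \code{stack} (rows x cols x frames array),
#'   \code{bleachTimes} (per-molecule, seconds) and \code{fociTable}.
#' @export
generateBurstStack <- function(cells, fociTable, copies, nFrames = 40L,
                               dt = 0.034, tauBleach = 0.5, config,
                               seed = 1L) {
  stopifnot(is(cells, "CellSet"))
  nc <- length(cells)
  copies <- rep_len(copies, nc)
  n <- config@frameSizePx
  stack <- array(0, c(n, n, nFrames))
  molFocus <- rep(seq_len(nrow(fociTable)), fociTable$n_molecules)
  bleach <- withSeed(childSeed(seed, 11),
                     stats::rexp(length(molFocus), 1 / tauBleach))
  ids <- vapply(cells@cells, cellId, character(1))
  for (fr in seq_len(nFrames)) {
    tMid <- (fr - 0.5) * dt
    # per-focus emitting molecule count this frame (fraction of frame lit)
    lit <- pmin(1, pmax(0, (bleach - (fr - 1) * dt) / dt))
    nmol <- vapply(seq_len(nrow(fociTable)),
                   function(j) sum(lit[molFocus == j]), numeric(1))
    ft <- fociTable
    ft$n_molecules <- nmol
    ft <- ft[nmol > 0, , drop = FALSE]
    boundPerCell <- vapply(ids, function(id)
      sum(fociTable$n_molecules[fociTable$cell_id == id]), numeric(1))
    freeNow <- pmax(0, copies - boundPerCell) * exp(-tMid / tauBleach)
    afNow <- config@autofluorescenceEquiv * exp(-tMid / tauBleach)
    stack[, , fr] <- renderFrame(
      cells, ft, frameSizePx = n, pixelSize = config@pixelSize,
      psfSigmaPx = config@psfSigmaPx, unitIntensity = config@unitIntensity,
      freeCopies = freeNow, autofluorescenceEquiv = afNow,
      snr = config@snr, offset = config@offset,
      readNoiseSd = config@readNoiseSd, seed = childSeed(seed, 12, fr))
  }
  list(stack = stack, bleachTimes = bleach, fociTable = fociTable)
}
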