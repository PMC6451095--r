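#' Construct a trajectory-simulator configuration
#'
#' Defaults give 300 frames of 34 ms (the burst-acquisition geometry),
#' complex binding kinetics with a mean autocorrelation timescale of order
#' a second, permanently bound molecules (no exchange), a 5 s mean bleach
#' lifetime and single-molecule signal-to-noise of 3.
#'
#' @param nMolPerComplex molecules per complex (>= 1).
#' @param kOnComplex,kOffComplex DNA binding/unbinding rates (1/s).
#' @param kOnMolecule,kOffMolecule molecule exchange rates on the complex
#'   (1/s); \code{kOffMolecule = 0} means permanently bound molecules.
#' @param tauBleach mean photobleaching time (s).
#' @param snr per-frame mean/sd of the one-molecule signal.
#' @param nFrames frames per trajectory.
#' @param dt frame time (s).
#' @param bleachClock \code{"illumination"} (default: the bleach clock runs
#'   only while the molecule emits, as under continuous excitation) or
#'   \code{"wall"}.
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nMolPerComplex = 1L, kOnComplex = 0.2,
                             kOffComplex = 0.5, kOnMolecule = 1,
                             kOffMolecule = 0, tauBleach = 5, snr = 3,
                             nFrames = 300L, dt = 0.034,
                             bleachClock = c("illumination", "wall"),
                             seed = 1L) {
  methods::new("SimulationConfig",
               nMolPerComplex = as.integer(nMolPerComplex),
               kOnComplex = kOnComplex, kOffComplex = kOffComplex,
               kOnMolecule = kOnMolecule, kOffMolecule = kOffMolecule,
               tauBleach = tauBleach, snr = snr,
               nFrames = as.integer(nFrames), dt = dt,
               bleachClock = match.arg(bleachClock), seed = as.integer(seed))
}

#' Simulate a two-state (telegraph) occupancy trajectory
#'
#' Continuous-time two-state Markov chain with exponential dwell times
#' (rate \code{kOn} to bind, \code{kOff} to unbind), initialized from the
#' stationary distribution and integrated onto the frame grid: each frame
#' reports the fraction of the frame time spent bound, which is more
#' faithful than per-frame Bernoulli switching when dwell times approach
#' \code{dt}.
#'
#' @param kOn,kOff rates in 1/s (not both zero).
#' @param nFrames number of frames.
#' @param dt frame time (s).
#' @param seed optional integer seed.
#' @return numeric vector of per-frame occupancies in [0, 1].
#' @examples
#' occ <- simulateStateTrajectory(1, 1, 1000, 0.034, seed = 1)
#' mean(occ)  # ~ kOn / (kOn + kOff) = 0.5
#' @export
simulateStateTrajectory <- function(kOn, kOff, nFrames, dt, seed = NULL) {
  stopIfNot(kOn >= 0 && kOff >= 0, "rates must be >= 0")
  stopIfNot(kOn + kOff > 0,
            "kOn and kOff cannot both be zero (stationary state undefined)")
  nFrames <- as.integer(nFrames)
  total <- nFrames * dt
  withSeed(seed, {
    state <- stats::runif(1) < kOn / (kOn + kOff)  # stationary init
    # absorbing edge cases
    if ((state && kOff == 0) || (!state && kOn == 0))
      return(rep(as.numeric(state), nFrames))
    tNow <- 0
    times <- numeric(0); states <- logical(0)
    s <- state
    while (tNow < total) {
      rate <- if (s) kOff else kOn
      if (rate == 0) break
      tNow <- tNow + stats::rexp(1, rate)
      s <- !s
      times <- c(times, tNow); states <- c(states, s)
      if ((s && kOff == 0) || (!s && kOn == 0)) break
    }
    occupancyFromEvents(state, times, nFrames, dt)
  })
}

# Integrate a piecewise-constant binary state onto the frame grid.
# `initState` holds from 0 until times[1], after which state flips at each
# event time. Returns per-frame mean occupancy.
occupancyFromEvents <- function(initState, times, nFrames, dt) {
  total <- nFrames * dt
  edges <- c(0, pmin(times, total), total)
  edges <- edges[!duplicated(edges)]
  segState <- rep(c(initState, !initState),
                  length.out = length(edges) - 1)
  # accumulate bound time per frame
  occ <- numeric(nFrames)
  for (k in seq_along(segState)) {
    if (!segState[k]) next
    a <- edges[k]; b <- edges[k + 1]
    if (b <= a) next
    f0 <- floor(a / dt); f1 <- ceiling(b / dt) - 1
    for (f in f0:f1) {
      lo <- max(a, f * dt); hi <- min(b, (f + 1) * dt)
      if (hi > lo && f < nFrames) occ[f + 1] <- occ[f + 1] + (hi - lo)
    }
  }
  occ / dt
}

#' Draw photobleaching lifetimes
#'
#' One exponential bleach time per molecule with mean \code{tauBleach}.
#' The returned times are budgets of emitting time: downstream composition
#' counts them down only while the molecule is actually producing signal
#' (illumination-coupled clock) unless the wall-clock mode is selected.
#'
#' @param tauBleach mean bleach time (s), > 0.
#' @param nMolecules number of molecules (>= 0).
#' @param seed optional seed.
#' @return numeric vector of bleach times (s), length \code{nMolecules}.
#' @export
simulatePhotobleaching <- function(tauBleach, nMolecules, seed = NULL) {
  stopIfNot(is.numeric(tauBleach) && tauBleach > 0,
            "tauBleach must be > 0")
  nMolecules <- as.integer(nMolecules)
  if (nMolecules == 0L) return(numeric(0))
  withSeed(seed, stats::rexp(nMolecules, 1 / tauBleach))
}

#' Compose a noisy intensity trajectory from its stochastic parts
#'
#' A molecule produces signal in a frame only in proportion to the time it
#' is simultaneously bound to the complex, the complex is bound to DNA and
#' the molecule is unbleached. Per-frame emitting fractions are multiplied
#' (complex x molecule occupancy), the bleach budget is spent against the
#' emitting time (or against wall time with \code{bleachClock = "wall"}),
#' and Poissonian noise is applied per molecule with scale \code{snr^2}
#' photons per single-molecule frame, so one molecule has per-frame
#' mean/sd = \code{snr} and k simultaneously emitting molecules have
#' k-fold variance (relative noise shrinking as 1/sqrt(k)).
#'
#' @param complexOccupancy numeric vector, per-frame complex-on-DNA
#'   fraction.
#' @param moleculeOccupancies matrix (frames x molecules) of per-frame
#'   molecule-on-complex fractions.
#' @param bleachTimes numeric vector, one bleach budget (s) per molecule.
#' @param snr signal-to-noise; \code{Inf} disables noise.
#' @param dt frame time (s).
#' @param bleachClock \code{"illumination"} or \code{"wall"}.
#' @param noise logical; FALSE returns the noise-free signal.
#' @param seed optional seed.
#' @return numeric vector of per-frame intensities in single-molecule
#'   units.
#' @export
composeTrajectory <- function(complexOccupancy, moleculeOccupancies,
                              bleachTimes, snr = 3, dt = 0.034,
                              bleachClock = c("illumination", "wall"),
                              noise = TRUE, seed = NULL) {
  bleachClock <- match.arg(bleachClock)
  if (is.vector(moleculeOccupancies))
    moleculeOccupancies <- matrix(moleculeOccupancies, ncol = 1)
  nF <- length(complexOccupancy)
  stopIfNot(nrow(moleculeOccupancies) == nF,
            "complex and molecule occupancies must share the frame grid")
  nMol <- ncol(moleculeOccupancies)
  stopIfNot(length(bleachTimes) == nMol,
            "need one bleach time per molecule")
  sig <- numeric(nF)
  emitting <- moleculeOccupancies * complexOccupancy
  for (m in seq_len(nMol)) {
    em <- emitting[, m]
    clockRate <- if (bleachClock == "illumination") em else rep(1, nF)
    spent <- cumsum(clockRate) * dt
    # fraction of each frame before the bleach budget is exhausted
    aliveFrac <- pmin(1, pmax(0, (bleachTimes[m] - (spent - clockRate * dt)) /
                                   pmax(clockRate * dt, .Machine$double.eps)))
    aliveFrac[clockRate == 0] <- 1
    aliveFrac[spent - clockRate * dt >= bleachTimes[m]] <- 0
    sig <- sig + em * aliveFrac
  }
  if (!noise || !is.finite(snr)) return(sig)
  withSeed(seed, {
    lambda <- sig * snr^2
    stats::rpois(nF, lambda) / snr^2
  })
}

#' Simulate an ensemble of intensity trajectories
#'
#' Runs the three simulator stages per trajectory (complex binding,
#' molecule exchange, photobleaching) and composes noisy signals.
#'
#' @param config a [SimulationConfig-class].
#' @param nTraj number of trajectories.
#' @param noise logical, apply Poisson noise.
#' @return a [TrajectorySet-class] (frames x trajectories).
#' @export
simulateTrajectories <- function(config, nTraj, noise = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  methods::validObject(config)
  nF <- config@nFrames
  out <- matrix(0, nF, nTraj)
  for (j in seq_len(nTraj)) {
    s1 <- childSeed(config@seed, 21, j)
    comp <- simulateStateTrajectory(config@kOnComplex, config@kOffComplex,
                                    nF, config@dt, seed = s1)
    mol <- matrix(0, nF, config@nMolPerComplex)
    for (m in seq_len(config@nMolPerComplex)) {
      if (config@kOffMolecule == 0 && config@kOnMolecule > 0) {
        mol[, m] <- 1
      } else {
        mol[, m] <- simulateStateTrajectory(
          config@kOnMolecule, config@kOffMolecule, nF, config@dt,
          seed = childSeed(config@seed, 22, j, m))
      }
    }
    bl <- simulatePhotobleaching(config@tauBleach, config@nMolPerComplex,
                                 seed = childSeed(config@seed, 23, j))
    out[, j] <- composeTrajectory(comp, mol, bl, snr = config@snr,
                                  dt = config@dt,
                                  bleachClock = config@bleachClock,
                                  noise = noise,
                                  seed = childSeed(config@seed, 24, j))
  }
  methods::new("TrajectorySet", intensities = out, dt = config@dt,
               origin = "simulated")
}

#' One- versus two-molecule complex comparison
#'
#' Simulates matched trajectory ensembles in which every complex
#' permanently carries either one or two molecules, with all other
#' parameters held constant, then averages their autocorrelation functions
#' and decomposes each mean ACF. Doubling the molecules per focus raises
#' the signal-to-noise of bound intervals, which appears as a reduction in
#' the fast-decorrelating (short) amplitude a_s.
#'
#' @param config a [SimulationConfig-class]; \code{nMolPerComplex} is
#'   overridden per ensemble and molecules are made permanent
#'   (\code{kOffMolecule = 0}).
#' @param nTraj trajectories per ensemble (>= 50 recommended, >= 2
#'   required).
#' @param fitStart first lag (s) of the exponential fit.
#' @return list with \code{monomer}/\code{dimer} [TrajectorySet-class]s,
#'   mean [AcfCurve-class]s \code{acfMonomer}/\code{acfDimer} and
#'   [AcfDecomposition-class]s \code{fitMonomer}/\code{fitDimer}.
#' @export
simulateDimerComparison <- function(config, nTraj = 150L,
                                    fitStart = 0.034) {
  stopIfNot(nTraj >= 2, "need at least 2 trajectories per ensemble")
  ens <- lapply(c(1L, 2L), function(nm) {
    cfg <- config
    cfg@nMolPerComplex <- nm
    cfg@kOffMolecule <- 0
    cfg@kOnMolecule <- max(cfg@kOnMolecule, 1)
    simulateTrajectories(cfg, nTraj, noise = TRUE)
  })
  acfs <- lapply(ens, function(ts) {
    curves <- autocorrelation(ts)
    meanAcf(curves)
  })
  fits <- lapply(acfs, fitAcfDecomposition, fitStart = fitStart)
  list(monomer = ens[[1]], dimer = ens[[2]],
       acfMonomer = acfs[[1]], acfDimer = acfs[[2]],
       fitMonomer = fits[[1]], fitDimer = fits[[2]])
}
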