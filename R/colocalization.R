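#' Directional two-channel colocalization
#'
#' An A focus is colocalized "with B" when at least one B centroid in the
#' same cell lies within the search radius (boundary inclusive); the
#' opposite direction is computed independently, so the two percentages are
#' generally asymmetric (they weight by different focus counts). The
#' default radius of 218 nm (2.18 px at 100 nm pixels) is the maximum
#' centroid distance observed between two replisome probes expected to be
#' fully colocalized. Matching is "at least one partner", not one-to-one
#' assignment, and never crosses cell boundaries.
#'
#' @param fociA,fociB [FocusSet-class] or focus data.frames of one shared
#'   time point.
#' @param radiusNm search radius in nm.
#' @param cells optional [CellSet-class] to add analytic chance baselines.
#' @return list with \code{summary} (one-row data.frame: counts,
#'   directional percentages, chance percentages when cells are supplied)
#'   and \code{pairs} (matched A-B pairs with distances in nm).
#' @export
colocalize <- function(fociA, fociB, radiusNm = 218, cells = NULL) {
  a <- if (is(fociA, "FocusSet")) foci(fociA) else fociA
  b <- if (is(fociB, "FocusSet")) foci(fociB) else fociB
  tps <- unique(c(a$time_point, b$time_point))
  stopIfNot(length(tps) <= 1,
            "foci span several time points; use colocalizationTimecourse()")
  rUm <- radiusNm / 1000
  tol <- 1e-9
  pairs <- list()
  withB <- rep(FALSE, nrow(a)); withA <- rep(FALSE, nrow(b))
  for (id in intersect(unique(a$cell_id), unique(b$cell_id))) {
    ia <- which(a$cell_id == id); ib <- which(b$cell_id == id)
    d <- sqrt(outer(a$x_um[ia], b$x_um[ib], "-")^2 +
                outer(a$y_um[ia], b$y_um[ib], "-")^2)
    hit <- d <= rUm + tol
    withB[ia] <- withB[ia] | rowSums(hit) > 0
    withA[ib] <- withA[ib] | colSums(hit) > 0
    if (any(hit)) {
      w <- which(hit, arr.ind = TRUE)
      pairs[[length(pairs) + 1L]] <- data.frame(
        cell_id = id, a_index = ia[w[, 1]], b_index = ib[w[, 2]],
        distance_nm = d[w] * 1000, stringsAsFactors = FALSE)
    }
  }
  summary <- data.frame(
    time_point = if (length(tps)) tps else NA_real_,
    n_A = nrow(a), n_B = nrow(b),
    pct_A_with_B = if (nrow(a)) 100 * mean(withB) else NA_real_,
    pct_B_with_A = if (nrow(b)) 100 * mean(withA) else NA_real_,
    radius_nm = radiusNm)
  if (!is.null(cells)) {
    summary$chance_pct_A_with_B <- chanceColocalization(cells, b, radiusNm)
    summary$chance_pct_B_with_A <- chanceColocalization(cells, a, radiusNm)
  }
  list(summary = summary,
       pairs = if (length(pairs)) do.call(rbind, pairs) else data.frame(
         cell_id = character(0), a_index = integer(0), b_index = integer(0),
         distance_nm = numeric(0)))
}

#' Analytic chance-colocalization baseline
#'
#' Expected directional colocalization if query foci were placed at random:
#' per cell, the fraction of the cell area covered by partner-focus search
#' disks, \code{min(1, n_B * pi * r^2 / area)}, averaged over cells and
#' expressed in percent. Disk overlap is ignored (summed with a per-cell
#' clamp at 1), a good approximation at the low focus densities this
#' baseline is meant for; one focus in a ~3.7 um^2 cell gives the familiar
#' ~4 percent at 218 nm. Cells without partner foci contribute zero, so the
#' baseline correctly reflects populations in which many cells have no
#' partner focus at all.
#'
#' @param cells a [CellSet-class] (areas > 0).
#' @param fociB partner-channel [FocusSet-class] or data.frame.
#' @param radiusNm search radius in nm.
#' @return percentage.
#' @examples
#' cl <- generateCell(3.9446, 1)  # area 3.73 um^2
#' fB <- placeFoci(cl, 1, "uniform", channel = "B", seed = 1)
#' chanceColocalization(new("CellSet", cells = list(cl)), fB)  # ~4.0
#' @export
chanceColocalization <- function(cells, fociB, radiusNm = 218) {
  stopifnot(is(cells, "CellSet"))
  b <- if (is(fociB, "FocusSet")) foci(fociB) else fociB
  rUm <- radiusNm / 1000
  fracs <- vapply(cells@cells, function(cell) {
    stopIfNot(cell@area > 0, "cell with zero area")
    nB <- sum(b$cell_id == cell@cellId)
    min(1, nB * pi * rUm^2 / cell@area)
  }, numeric(1))
  100 * mean(fracs)
}

#' Equal-area distance histogram
#'
#' Colocalization is a radial measurement, so distance histograms are
#' binned with edges of linearly increasing enclosed area,
#' \code{r_k = radiusMax * sqrt(k / nBins)}: every annulus covers the same
#' area and a uniform random scatter gives a flat histogram.
#'
#' @param distancesNm pair distances in nm (>= 0); distances beyond
#'   \code{radiusMaxNm} are not counted.
#' @param radiusMaxNm outer radius (default 218 nm).
#' @param nBins number of annuli (>= 1).
#' @return data.frame with lower/upper edges (nm) and counts.
#' @examples
#' areaShellHistogram(c(50, 120, 200), 218, 4)
#' @export
areaShellHistogram <- function(distancesNm, radiusMaxNm = 218, nBins = 10L) {
  stopIfNot(nBins >= 1, "nBins must be >= 1")
  stopIfNot(all(distancesNm >= 0), "distances must be >= 0")
  edges <- radiusMaxNm * sqrt(seq(0, nBins) / nBins)
  d <- distancesNm[distancesNm <= radiusMaxNm + 1e-9]
  counts <- if (length(d))
    as.integer(table(cut(d, breaks = edges, include.lowest = TRUE)))
  else rep(0L, nBins)
  data.frame(lower_nm = edges[-length(edges)], upper_nm = edges[-1],
             count = counts)
}

#' Colocalization time course
#'
#' Runs [colocalize()] at every shared time point of two focus tables,
#' attaching analytic chance baselines per time point. Time points missing
#' one channel are skipped with a warning.
#'
#' @param fociA,fociB [FocusSet-class] or focus data.frames spanning time
#'   points.
#' @param cellsByTime list of [CellSet-class] named or indexed by time
#'   point (as produced by [generateTimelapse()]), or NULL to skip chance
#'   baselines.
#' @param radiusNm search radius in nm.
#' @return data.frame, one row per analysed time point.
#' @export
colocalizationTimecourse <- function(fociA, fociB, cellsByTime = NULL,
                                     radiusNm = 218) {
  a <- if (is(fociA, "FocusSet")) foci(fociA) else fociA
  b <- if (is(fociB, "FocusSet")) foci(fociB) else fociB
  tps <- sort(unique(c(a$time_point, b$time_point)))
  rows <- list()
  for (ti in seq_along(tps)) {
    t <- tps[ti]
    at <- a[a$time_point == t, , drop = FALSE]
    bt <- b[b$time_point == t, , drop = FALSE]
    if (!nrow(at) || !nrow(bt)) {
      warning(sprintf("time point %g min missing a channel; skipped", t),
              call. = FALSE)
      next
    }
    cs <- NULL
    if (!is.null(cellsByTime)) {
      hit <- which(vapply(cellsByTime, function(s)
        length(s) > 0 && abs(s[[1]]@timePoint - t) < 1e-9, logical(1)))
      if (length(hit)) cs <- cellsByTime[[hit[1]]]
    }
    rows[[length(rows) + 1L]] <- colocalize(at, bt, radiusNm, cs)$summary
  }
  stopIfNot(length(rows) > 0, "no time point had both channels")
  do.call(rbind, rows)
}
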