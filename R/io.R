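#' TIFF stack input/output
#'
#' Writes a list of frames (or a rows x cols x frames array) as one
#' multi-page 16-bit TIFF per channel and reads such stacks back as a 3D
#' array of counts. Counts are stored as 16-bit integers (values clipped
#' to 0..65535).
#'
#' @param frames list of 2D matrices or a 3D array of counts.
#' @param path output file.
#' @return \code{writeTiffStack} returns \code{path} invisibly;
#'   \code{readTiffStack} returns a 3D array of counts.
#' @export
writeTiffStack <- function(frames, path) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  pages <- lapply(frames, function(f) {
    m <- pmin(pmax(round(f), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeTiffStack
#' @export
readTiffStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
  arr
}

#' Cell-outline tables
#'
#' Outlines are exchanged as plain CSV with one row per polygon vertex:
#' \code{cell_id, time_point, vertex_index, x_um, y_um}. Derived lengths,
#' widths, areas and volumes are recomputed on read from the polygon (the
#' spherocylinder volume uses the measured length/width).
#'
#' @param cells a [CellSet-class].
#' @param path CSV file path.
#' @return \code{writeOutlinesCsv} returns \code{path} invisibly;
#'   \code{readOutlinesCsv} a [CellSet-class].
#' @export
writeOutlinesCsv <- function(cells, path) {
  stopifnot(is(cells, "CellSet"))
  rows <- do.call(rbind, lapply(cells@cells, function(cell) {
    v <- cell@vertices
    data.frame(cell_id = cell@cellId, time_point = cell@timePoint,
               vertex_index = seq_len(nrow(v)), x_um = v[, 1],
               y_um = v[, 2], stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOutlinesCsv
#' @export
readOutlinesCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_point", "vertex_index", "x_um", "y_um")
  stopIfNot(all(need %in% names(tab)),
            paste("outline CSV needs columns:", paste(need, collapse = ", ")))
  keys <- unique(tab[, c("cell_id", "time_point")])
  cells <- lapply(seq_len(nrow(keys)), function(k) {
    sub <- tab[tab$cell_id == keys$cell_id[k] &
                 tab$time_point == keys$time_point[k], ]
    sub <- sub[order(sub$vertex_index), ]
    poly <- cbind(x_um = sub$x_um, y_um = sub$y_um)
    if (any(abs(poly[1, ] - poly[nrow(poly), ]) > 1e-9))
      poly <- rbind(poly, poly[1, , drop = FALSE])
    cx <- mean(poly[-nrow(poly), 1]); cy <- mean(poly[-nrow(poly), 2])
    dx <- poly[-nrow(poly), 1] - cx; dy <- poly[-nrow(poly), 2] - cy
    ev <- eigen(stats::cov(cbind(dx, dy)), symmetric = TRUE)
    theta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    lp <- dx * cos(theta) + dy * sin(theta)
    wp <- -dx * sin(theta) + dy * cos(theta)
    len <- diff(range(lp)); wid <- diff(range(wp))
    methods::new("CellOutline", cellId = as.character(keys$cell_id[k]),
                 vertices = poly, length = max(len, wid),
                 width = min(len, wid), area = polygonArea(poly),
                 volume = spherocylinderVolume(max(len, wid),
                                               min(len, wid)),
                 timePoint = keys$time_point[k], centre = c(cx, cy),
                 theta = theta)
  })
  methods::new("CellSet", cells = cells)
}

#' Focus tables
#'
#' Focus records round-trip as CSV using the documented schema (cell_id,
#' channel, time_point, x_um, y_um plus any extra columns present, e.g.
#' x_px, intensity, snr, n_molecules).
#'
#' @param fociSet a [FocusSet-class].
#' @param path CSV file path.
#' @param pixelSize um per pixel stored on the read FocusSet.
#' @return \code{writeFociCsv} returns \code{path} invisibly;
#'   \code{readFociCsv} a [FocusSet-class].
#' @export
writeFociCsv <- function(fociSet, path) {
  stopifnot(is(fociSet, "FocusSet"))
  utils::write.csv(foci(fociSet), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFociCsv
#' @export
readFociCsv <- function(path, pixelSize = 0.1) {
  methods::new("FocusSet",
               records = utils::read.csv(path, stringsAsFactors = FALSE),
               pixelSize = pixelSize)
}

#' Trajectory tables
#'
#' Trajectories round-trip as long-format CSV with columns trajectory_id,
#' frame, time_s, intensity.
#'
#' @param trajectories a [TrajectorySet-class].
#' @param path CSV file path.
#' @return \code{writeTrajectoriesCsv} returns \code{path} invisibly;
#'   \code{readTrajectoriesCsv} a [TrajectorySet-class].
#' @export
writeTrajectoriesCsv <- function(trajectories, path) {
  stopifnot(is(trajectories, "TrajectorySet"))
  m <- intensities(trajectories)
  long <- data.frame(
    trajectory_id = rep(seq_len(ncol(m)), each = nrow(m)),
    frame = rep(seq_len(nrow(m)), ncol(m)),
    time_s = rep((seq_len(nrow(m)) - 1) * frameTime(trajectories), ncol(m)),
    intensity = as.vector(m))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoriesCsv
#' @param origin origin label for the read TrajectorySet.
#' @export
readTrajectoriesCsv <- function(path, origin = "measured") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "frame", "time_s", "intensity")
  stopIfNot(all(need %in% names(tab)),
            paste("trajectory CSV needs columns:",
                  paste(need, collapse = ", ")))
  ids <- sort(unique(tab$trajectory_id))
  nF <- max(tab$frame)
  m <- matrix(NA_real_, nF, length(ids))
  for (k in seq_along(ids)) {
    sub <- tab[tab$trajectory_id == ids[k], ]
    m[sub$frame, k] <- sub$intensity
  }
  stopIfNot(all(is.finite(m)), "trajectories must share one frame grid")
  dt <- if (nF > 1) tab$time_s[tab$frame == 2][1] - tab$time_s[tab$frame == 1][1]
        else 0.034
  methods::new("TrajectorySet", intensities = m, dt = dt, origin = origin)
}
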