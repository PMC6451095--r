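#' Generate a spherocylindrical cell outline
#'
#' Builds the closed polygon of a rod-shaped cell (a rectangle of length
#' \code{length - width} capped by two semicircles of diameter \code{width}),
#' the standard geometry used to model \emph{E. coli}. Area and volume are
#' derived from the spherocylinder closed forms, matching how cell volumes
#' are assigned during outline creation in live-cell analysis pipelines.
#'
#' @param length pole-to-pole length in um; must be >= \code{width}.
#' @param width short-axis width in um (> 0).
#' @param cellId identifier string.
#' @param centre numeric length-2, cell centre (x, y) in um.
#' @param theta orientation of the long axis in radians.
#' @param timePoint minutes relative to the damage event.
#' @param nVertices number of polygon vertices (>= 32).
#' @param seed unused; accepted so cell generation shares the calling
#'   convention of the other generators (the outline is deterministic).
#' @return a [CellOutline-class].
#' @examples
#' cl <- generateCell(3, 1)
#' cellArea(cl)    # (3 - 1) * 1 + pi * 0.25 = 2.785 um^2
#' cellVolume(cl)  # pi * 0.25 * 2 + (4/3) * pi * 0.125 = 2.094 fL
#' @export
generateCell <- function(length, width, cellId = "cell_1",
                         centre = c(length / 2 + width, width),
                         theta = 0, timePoint = 0, nVertices = 64L,
                         seed = NULL) {
  stopIfNot(is.numeric(length) && is.numeric(width) && width > 0 &&
              length >= width,
            "cell geometry requires length >= width > 0")
  stopIfNot(nVertices >= 32L, "nVertices must be >= 32")
  r <- width / 2
  ls <- length / 2 - r
  nCap <- ceiling(nVertices / 2)
  # right cap: -pi/2 -> pi/2, left cap: pi/2 -> 3pi/2
  a1 <- seq(-pi / 2, pi / 2, length.out = nCap)
  a2 <- seq(pi / 2, 3 * pi / 2, length.out = nCap)
  lx <- c(ls + r * cos(a1), -ls + r * cos(a2))
  wy <- c(r * sin(a1), r * sin(a2))
  g <- cbind(centre[1] + lx * cos(theta) - wy * sin(theta),
             centre[2] + lx * sin(theta) + wy * cos(theta))
  g <- rbind(g, g[1, , drop = FALSE])
  colnames(g) <- c("x_um", "y_um")
  methods::new("CellOutline", cellId = as.character(cellId), vertices = g,
               length = length, width = width,
               area = spherocylinderArea(length, width),
               volume = spherocylinderVolume(length, width),
               timePoint = timePoint, centre = as.numeric(centre),
               theta = theta)
}

#' Place ground-truth foci inside a cell
#'
#' Draws focus positions inside a spherocylindrical cell with one of three
#' short-axis placement modes. \code{"central"} concentrates foci on the
#' centre spline (>= 90 percent within 0.2 um of the spline for a 1-um wide
#' cell), emulating nucleoid/replisome-associated binding;
#' \code{"peripheral"} is bimodal with modes at +/- 0.3 um (scaled by the
#' cell width in um), emulating membrane-proximal binding; \code{"uniform"}
#' is uniform over the polygon. Along the long axis, positions are uniform
#' over the region of the cell compatible with the drawn width coordinate.
#'
#' @param cell a [CellOutline-class].
#' @param n number of foci (>= 0).
#' @param mode one of \code{"central"}, \code{"peripheral"},
#'   \code{"uniform"}.
#' @param stoichiometry molecules per focus (integer >= 1).
#' @param channel channel label stored with each focus.
#' @param seed optional integer seed.
#' @return data.frame with columns cell_id, channel, time_point, x_um,
#'   y_um, n_molecules, width_um (signed short-axis coordinate) and
#'   axial_um.
#' @examples
#' cl <- generateCell(3, 1)
#' f <- placeFoci(cl, 5, mode = "central", seed = 1)
#' all(abs(f$width_um) <= 0.5)
#' @export
placeFoci <- function(cell, n, mode = c("uniform", "central", "peripheral"),
                      stoichiometry = 1L, channel = "A", seed = NULL) {
  mode <- match.arg(mode)
  stopIfNot(is.numeric(n) && n >= 0, "n must be >= 0")
  n <- as.integer(n)
  emptyFoci <- function() data.frame(
    cell_id = character(0), channel = character(0), time_point = numeric(0),
    x_um = numeric(0), y_um = numeric(0), n_molecules = integer(0),
    width_um = numeric(0), axial_um = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) return(emptyFoci())
  L <- cell@length; W <- cell@width; r <- W / 2
  withSeed(seed, {
    drawWidth <- switch(mode,
      central = function(k) {
        # sd = 0.1 * W puts ~95% within 0.2 um of the spline for W = 1 um
        out <- numeric(0)
        while (length(out) < k) {
          w <- stats::rnorm(k, 0, 0.1 * W)
          out <- c(out, w[abs(w) < r * 0.99])
        }
        out[seq_len(k)]
      },
      peripheral = function(k) {
        out <- numeric(0)
        while (length(out) < k) {
          side <- sample(c(-1, 1), k, replace = TRUE)
          w <- stats::rnorm(k, side * 0.3 * W, 0.08 * W)
          out <- c(out, w[abs(w) < r * 0.99])
        }
        out[seq_len(k)]
      },
      uniform = NULL)
    if (mode == "uniform") {
      # rejection sampling over the local bounding box
      l <- numeric(0); w <- numeric(0)
      while (length(l) < n) {
        lc <- stats::runif(2L * n, -L / 2, L / 2)
        wc <- stats::runif(2L * n, -r, r)
        keep <- abs(wc) < spherocylinderHalfWidth(lc, L, W) * 0.99
        l <- c(l, lc[keep]); w <- c(w, wc[keep])
      }
      l <- l[seq_len(n)]; w <- w[seq_len(n)]
    } else {
      w <- drawWidth(n)
      # admissible axial extent given the width coordinate
      lmax <- (L / 2 - r + sqrt(pmax(0, r^2 - w^2))) * 0.995
      l <- stats::runif(n, -lmax, lmax)
    }
    g <- cellLocalToGlobal(cell, l, w)
    data.frame(cell_id = cell@cellId, channel = channel,
               time_point = cell@timePoint,
               x_um = g[, "x"], y_um = g[, "y"],
               n_molecules = as.integer(stoichiometry),
               width_um = w, axial_um = l, stringsAsFactors = FALSE)
  })
}
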