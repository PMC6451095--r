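## Internal helpers shared across modules.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched (still consumed).
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Derive a reproducible child seed; kept inside 32-bit integer range.
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (k in seq_along(idx)) s <- (s * 7919 + idx[k] * 104729 + 13) %% 2147483629
  as.integer(s)
}

# Point-in-polygon test; `poly` is a closed two-column matrix.
pointsInPolygon <- function(poly, x, y) {
  if (!length(x)) return(logical(0))
  mgcv::in.out(poly, cbind(as.numeric(x), as.numeric(y)))
}

# Shoelace polygon area (closed ring).
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Pixel centre coordinates (um) for an image matrix: x runs along columns,
# y along rows, pixel [i, j] has centre ((j - 0.5) * px, (i - 0.5) * px).
pixelCentres <- function(nrow, ncol, pixelSize) {
  list(x = (seq_len(ncol) - 0.5) * pixelSize,
       y = (seq_len(nrow) - 0.5) * pixelSize)
}

# Linear index set of pixels whose centres lie inside a cell polygon.
# Restricted to the polygon bounding box for speed.
pixelsInsideCell <- function(cell, dim, pixelSize) {
  v <- cell@vertices
  jr <- pmax(1L, pmin(dim[2], floor(range(v[, 1]) / pixelSize) + c(0L, 2L)))
  ir <- pmax(1L, pmin(dim[1], floor(range(v[, 2]) / pixelSize) + c(0L, 2L)))
  js <- jr[1]:jr[2]; is <- ir[1]:ir[2]
  grid <- expand.grid(i = is, j = js)
  gx <- (grid$j - 0.5) * pixelSize
  gy <- (grid$i - 0.5) * pixelSize
  keep <- pointsInPolygon(v, gx, gy)
  (grid$j[keep] - 1L) * dim[1] + grid$i[keep]
}

# Expand a linear-index pixel set by its 8-neighbourhood (one iteration),
# clipped to the image. Used so that foci sitting on the membrane, whose
# peak pixel centre falls just outside the polygon, are still searched.
dilatePx <- function(px, dim) {
  nr <- dim[1]; nc <- dim[2]
  i <- ((px - 1L) %% nr) + 1L
  j <- ((px - 1L) %/% nr) + 1L
  out <- integer(0)
  for (di in -1L:1L) for (dj in -1L:1L) {
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    out <- c(out, (jj[ok] - 1L) * nr + ii[ok])
  }
  sort(unique(out))
}

# Bilinear interpolation of image values at (x_px, y_px) pixel coordinates
# (same convention as pixelCentres; x_px = j - 0.5 at pixel centres).
bilinearInterp <- function(img, xPx, yPx) {
  nr <- nrow(img); nc <- ncol(img)
  jf <- pmin(pmax(xPx + 0.5, 1), nc)   # fractional column
  if0 <- pmin(pmax(yPx + 0.5, 1), nr)  # fractional row
  j0 <- pmin(floor(jf), nc - 1L); i0 <- pmin(floor(if0), nr - 1L)
  fx <- jf - j0; fy <- if0 - i0
  v00 <- img[cbind(i0, j0)];     v01 <- img[cbind(i0, j0 + 1L)]
  v10 <- img[cbind(i0 + 1L, j0)]; v11 <- img[cbind(i0 + 1L, j0 + 1L)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# 3x3 neighbourhood maximum via shifted copies (used for local maxima).
localMax3x3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- img
  best <- matrix(-Inf, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1 && dj == 1) next
    best <- pmax(best, pad[(1:nr) + di, (1:nc) + dj])
  }
  img > best
}

# Spherocylinder closed forms (length L, width W in um).
spherocylinderArea <- function(length, width)
  (length - width) * width + pi * (width / 2)^2

spherocylinderVolume <- function(length, width) {
  r <- width / 2
  pi * r^2 * (length - width) + (4 / 3) * pi * r^3
}

# Half-width of the spherocylinder at axial position l (|l| <= L/2).
spherocylinderHalfWidth <- function(l, length, width) {
  r <- width / 2
  ls <- length / 2 - r
  out <- rep(r, length(l))
  cap <- abs(l) > ls
  out[cap] <- sqrt(pmax(0, r^2 - (abs(l[cap]) - ls)^2))
  out
}

# Rotate local (l, w) coordinates into the image frame of a cell.
cellLocalToGlobal <- function(cell, l, w) {
  ct <- cos(cell@theta); st <- sin(cell@theta)
  cbind(x = cell@centre[1] + l * ct - w * st,
        y = cell@centre[2] + l * st + w * ct)
}

# Project image-frame points into cell-local (l, w) coordinates.
cellGlobalToLocal <- function(cell, x, y) {
  dx <- x - cell@centre[1]; dy <- y - cell@centre[2]
  ct <- cos(cell@theta); st <- sin(cell@theta)
  cbind(l = dx * ct + dy * st, w = -dx * st + dy * ct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
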