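#' Segment cells from a binary mask
#'
#' Minimal mask-based segmenter: connected-component labelling of a binary
#' mask, polygon extraction as the convex hull of each component's contour
#' (exact for the convex rod shapes this package models), and rejection of
#' components touching the frame border (mirroring manual curation of
#' non-overlapping, in-focus cells). Full-featured outline tools can be
#' used instead and their outlines imported with [readOutlinesCsv()].
#'
#' @param mask 2D numeric/logical matrix; nonzero is foreground.
#' @param pixelSize um per pixel.
#' @param timePoint minutes, stored on each outline.
#' @param minAreaPx discard components smaller than this (noise specks).
#' @return a [CellSet-class]; empty when the mask has no foreground.
#' @export
segmentCells <- function(mask, pixelSize = 0.1, timePoint = 0,
                         minAreaPx = 20L) {
  stopifnot(length(dim(mask)) == 2)
  bw <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(bw > 0)) return(methods::new("CellSet", cells = list()))
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  nr <- nrow(labm); nc <- ncol(labm)
  cells <- list()
  for (k in seq_len(max(labm))) {
    idx <- which(labm == k)
    if (length(idx) < minAreaPx) next
    i <- ((idx - 1L) %% nr) + 1L
    j <- ((idx - 1L) %/% nr) + 1L
    if (any(i == 1L | i == nr | j == 1L | j == nc)) next  # border cell
    # pixel centres in um; convex hull as the outline polygon
    x <- (j - 0.5) * pixelSize
    y <- (i - 0.5) * pixelSize
    hull <- grDevices::chull(x, y)
    poly <- cbind(x_um = x[hull], y_um = y[hull])
    poly <- rbind(poly, poly[1, , drop = FALSE])
    # principal axis from the pixel cloud
    cx <- mean(x); cy <- mean(y)
    cv <- stats::cov(cbind(x, y))
    ev <- eigen(cv, symmetric = TRUE)
    ax <- ev$vectors[, 1]
    theta <- atan2(ax[2], ax[1])
    lproj <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
    wproj <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
    # pixel-centre extent + one pixel to account for pixel footprints
    len <- diff(range(lproj)) + pixelSize
    wid <- diff(range(wproj)) + pixelSize
    area <- length(idx) * pixelSize^2
    cells[[length(cells) + 1L]] <- methods::new(
      "CellOutline", cellId = sprintf("cell_%03d", length(cells) + 1L),
      vertices = poly, length = max(len, wid), width = min(len, wid),
      area = area, volume = spherocylinderVolume(max(len, wid), min(len, wid)),
      timePoint = timePoint, centre = c(cx, cy), theta = theta)
  }
  methods::new("CellSet", cells = cells)
}

# Fit a 2D Gaussian around an integer-pixel candidate; returns refined
# centroid (um), integrated intensity and fitted sigma, or NULL. The fit is
# restricted to pixels inside the owning cell (`cellPx`, linear indices) so
# the sharp cell boundary cannot masquerade as a broad Gaussian.
fitGaussianPeak <- function(img, i0, j0, psfSigmaPx, pixelSize, bg,
                            cellPx = NULL) {
  half <- max(3L, ceiling(2.5 * psfSigmaPx))
  is <- max(1L, i0 - half):min(nrow(img), i0 + half)
  js <- max(1L, j0 - half):min(ncol(img), j0 + half)
  df <- data.frame(z = as.vector(img[is, js]) - bg,
                   i = rep(is, times = length(js)),
                   j = rep(js, each = length(is)))
  if (!is.null(cellPx)) {
    lin <- (df$j - 1L) * nrow(img) + df$i
    inCell <- lin %in% cellPx
    if (sum(inCell) >= 12L) df <- df[inCell, , drop = FALSE]
  }
  start <- list(A = max(df$z), x0 = j0 - 0.5, y0 = i0 - 0.5,
                s = psfSigmaPx, b = 0)
  fit <- tryCatch(minpack.lm::nlsLM(
    z ~ A * exp(-(((j - 0.5) - x0)^2 + ((i - 0.5) - y0)^2) / (2 * s^2)) + b,
    data = df, start = start,
    lower = c(0, j0 - 0.5 - half, i0 - 0.5 - half, 0.5 * psfSigmaPx, -Inf),
    upper = c(Inf, j0 - 0.5 + half, i0 - 0.5 + half, 2.5 * psfSigmaPx, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # intensity-weighted centroid fallback
    zp <- pmax(df$z, 0)
    if (sum(zp) <= 0) return(NULL)
    x0 <- sum((df$j - 0.5) * zp) / sum(zp)
    y0 <- sum((df$i - 0.5) * zp) / sum(zp)
    return(list(list(xUm = x0 * pixelSize, yUm = y0 * pixelSize,
                     amp = max(zp), integrated = sum(zp),
                     sigma = psfSigmaPx)))
  }
  co <- stats::coef(fit)
  single <- list(xUm = unname(co["x0"]) * pixelSize,
                 yUm = unname(co["y0"]) * pixelSize,
                 amp = unname(co["A"]),
                 integrated = unname(2 * pi * co["A"] * co["s"]^2),
                 sigma = unname(co["s"]))
  # a broad fit often means two unresolved emitters: attempt a
  # two-component deconvolution with the PSF sigma fixed and keep it if
  # it clearly wins on AIC
  if (single$sigma > 1.08 * psfSigmaPx) {
    zp <- pmax(df$z, 0)
    mx <- sum((df$j - 0.5) * zp) / sum(zp)
    my <- sum((df$i - 0.5) * zp) / sum(zp)
    cxx <- sum(((df$j - 0.5) - mx)^2 * zp) / sum(zp)
    cyy <- sum(((df$i - 0.5) - my)^2 * zp) / sum(zp)
    cxy <- sum(((df$j - 0.5) - mx) * ((df$i - 0.5) - my) * zp) / sum(zp)
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)
    ux <- ev$vectors[1, 1]; uy <- ev$vectors[2, 1]
    off <- 1.2 * psfSigmaPx
    s2 <- psfSigmaPx
    fit2 <- tryCatch(minpack.lm::nlsLM(
      z ~ A1 * exp(-(((j - 0.5) - xa)^2 + ((i - 0.5) - ya)^2) / (2 * s2^2)) +
          A2 * exp(-(((j - 0.5) - xb)^2 + ((i - 0.5) - yb)^2) / (2 * s2^2)) + b,
      data = df,
      start = list(A1 = single$amp, xa = mx + off * ux, ya = my + off * uy,
                   A2 = single$amp, xb = mx - off * ux, yb = my - off * uy,
                   b = 0),
      lower = c(0, mx - 6, my - 6, 0, mx - 6, my - 6, -Inf),
      upper = c(Inf, mx + 6, my + 6, Inf, mx + 6, my + 6, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (!is.null(fit2) && stats::BIC(fit2) < stats::BIC(fit)) {
      c2 <- stats::coef(fit2)
      sep2 <- (c2["xa"] - c2["xb"])^2 + (c2["ya"] - c2["yb"])^2
      # both components must be supported by data: amplitudes bounded by
      # the observed excess and centres inside the fitted pixel region
      # (otherwise a component can extrapolate into the cell boundary)
      supported <- function(xc, yc)
        min((df$j - 0.5 - xc)^2 + (df$i - 0.5 - yc)^2) <= 1
      if (sep2 > (1.8 * psfSigmaPx / 1.3)^2 && c2["A1"] > 0 && c2["A2"] > 0 &&
          max(c2["A1"], c2["A2"]) <= 2 * max(df$z) &&
          supported(c2["xa"], c2["ya"]) && supported(c2["xb"], c2["yb"])) {
        return(list(
          list(xUm = unname(c2["xa"]) * pixelSize,
               yUm = unname(c2["ya"]) * pixelSize, amp = unname(c2["A1"]),
               integrated = unname(2 * pi * c2["A1"] * s2^2), sigma = s2,
               split = TRUE),
          list(xUm = unname(c2["xb"]) * pixelSize,
               yUm = unname(c2["yb"]) * pixelSize, amp = unname(c2["A2"]),
               integrated = unname(2 * pi * c2["A2"] * s2^2), sigma = s2,
               split = TRUE)))
      }
    }
  }
  list(single)
}

#' Detect diffraction-limited foci inside cell outlines
#'
#' Candidate peaks are local maxima of the focus-enhanced image (see
#' [enhanceFoci()]) inside a cell outline exceeding the per-cell background
#' by \code{minPeakSnr} times the per-cell robust noise. Candidates are
#' refined by least-squares 2D Gaussian fitting (intensity-weighted
#' centroid fallback), merged when closer than one PSF sigma, and reported
#' with background-subtracted integrated intensities. The per-cell
#' background is the median intensity inside the outline excluding
#' 3-sigma disks around candidate peaks.
#'
#' @param image 2D matrix of camera counts.
#' @param cells a [CellSet-class] in the same coordinate frame.
#' @param minPeakSnr detection threshold in noise sigmas (> 0).
#' @param psfSigmaPx PSF sigma in pixels.
#' @param pixelSize um per pixel.
#' @param channel,timePoint labels stored on the records.
#' @return a [FocusSet-class].
#' @export
detectFoci <- function(image, cells, minPeakSnr = 3, psfSigmaPx = 1.3,
                       pixelSize = 0.1, channel = "A", timePoint = 0) {
  stopIfNot(is.numeric(minPeakSnr) && minPeakSnr > 0,
            "minPeakSnr must be > 0")
  stopifnot(is(cells, "CellSet"))
  enh <- enhanceFoci(image, sigma1 = psfSigmaPx)
  isMax <- localMax3x3(enh)
  nr <- nrow(image)
  rec <- list()
  for (k in seq_len(length(cells))) {
    cell <- cells[[k]]
    px <- pixelsInsideCell(cell, dim(image), pixelSize)
    if (length(px) < 9L) next
    pxSearch <- dilatePx(px, dim(image))
    cellEnh <- enh[px]
    noiseEnh <- stats::mad(cellEnh)
    if (noiseEnh <= 0) noiseEnh <- stats::sd(cellEnh)
    if (!isTRUE(noiseEnh > 0)) next
    # lenient candidate gate (the MAD over the whole cell is inflated when
    # many foci are present); the fitted amplitude decides acceptance
    # below. Searching the one-pixel dilation keeps membrane-adjacent
    # peaks whose maximum falls between polygon and pixel grid.
    cand <- pxSearch[isMax[pxSearch] & enh[pxSearch] > 2 * noiseEnh]
    if (!length(cand)) next
    ci <- ((cand - 1L) %% nr) + 1L
    cj <- ((cand - 1L) %/% nr) + 1L
    # background excluding 3-sigma disks around candidates; in crowded
    # cells little remains and a low quantile of all pixels is safer
    pi0 <- ((px - 1L) %% nr) + 1L
    pj0 <- ((px - 1L) %/% nr) + 1L
    excl <- rep(FALSE, length(px))
    for (q in seq_along(cand))
      excl <- excl | ((pi0 - ci[q])^2 + (pj0 - cj[q])^2 <=
                        (3 * psfSigmaPx)^2)
    bgPix <- image[px[!excl]]
    if (length(bgPix) >= 20L) {
      bg <- stats::median(bgPix)
      noiseRaw <- stats::mad(bgPix)
    } else {
      bg <- stats::quantile(image[px], 0.3, names = FALSE)
      noiseRaw <- stats::mad(image[px][image[px] <= bg] - bg)
    }
    # floor: the left-tail fallback can collapse in cells where the
    # candidate disks cover almost every pixel
    noiseRaw <- max(noiseRaw, 0.5 * stats::mad(image[px]), 1e-6)
    # band-pass noise from background-only pixels: the enhanced image is a
    # matched filter for PSF-sized spots, so its peak SNR separates real
    # foci from single-pixel noise spikes far better than the raw peak
    noiseEnhBg <- if (sum(!excl) >= 20L) stats::mad(enh[px[!excl]])
                  else noiseEnh
    if (!isTRUE(noiseEnhBg > 0)) noiseEnhBg <- noiseEnh
    # the raw peak itself must clear the background: guards against both
    # boundary ringing of the band-pass image and noise maxima whose
    # fitted amplitude overshoots (free local offset). Peaks that fail
    # only because they sit on the membrane (where the diffuse cell
    # background is not under the peak pixel) get a second chance below
    # via a stricter fitted-amplitude gate.
    strong <- image[cand] - bg > minPeakSnr * noiseRaw &
      enh[cand] > (minPeakSnr + 1) * noiseEnhBg
    subtractComp <- function(img, f) {
      x0 <- f$xUm / pixelSize; y0 <- f$yUm / pixelSize
      jw <- max(1L, floor(x0 - 5 * psfSigmaPx)):min(ncol(img),
                                                    ceiling(x0 + 5 * psfSigmaPx))
      iw <- max(1L, floor(y0 - 5 * psfSigmaPx)):min(nrow(img),
                                                    ceiling(y0 + 5 * psfSigmaPx))
      gx <- exp(-((jw - 0.5) - x0)^2 / (2 * f$sigma^2))
      gy <- exp(-((iw - 0.5) - y0)^2 / (2 * f$sigma^2))
      img[iw, jw] <- img[iw, jw] - f$amp * outer(gy, gx)
      img
    }
    # fit candidates brightest-first, subtracting each accepted spot from
    # the working image so overlapping candidates cannot double-count the
    # same photons
    work <- image
    fits <- list()
    fitSequential <- function(cand, strong) {
      for (q in order(enh[cand], decreasing = TRUE)) {
        comps <- fitGaussianPeak(work, ci[q], cj[q], psfSigmaPx,
                                 pixelSize, bg, cellPx = px)
        if (is.null(comps)) next
        ampGate <- if (strong[q]) (minPeakSnr + 1) * noiseRaw
                   else (minPeakSnr + 3) * noiseRaw
        for (f in comps) {
          if (f$integrated <= 0) next
          if (f$amp < ampGate) next
          # boundary steps fit as oversized or runaway Gaussians
          if (f$sigma > 2 * psfSigmaPx) next
          # runaway guard for single fits; split components are displaced
          # from the shared candidate by construction
          if (is.null(f$split) &&
              (f$xUm / pixelSize - (cj[q] - 0.5))^2 +
              (f$yUm / pixelSize - (ci[q] - 0.5))^2 > 3^2) next
          # aggregate significance: the background-subtracted flux inside
          # a 2-sigma disk must clear the accumulated pixel noise; single
          # bright pixels fail this even when their peak passes
          rD <- 2 * psfSigmaPx
          jD <- max(1L, floor(f$xUm / pixelSize - rD)):
            min(ncol(work), ceiling(f$xUm / pixelSize + rD + 1))
          iD <- max(1L, floor(f$yUm / pixelSize - rD)):
            min(nr, ceiling(f$yUm / pixelSize + rD + 1))
          dd <- outer(((iD - 0.5) - f$yUm / pixelSize)^2,
                      ((jD - 0.5) - f$xUm / pixelSize)^2, "+")
          lin <- outer(iD, (jD - 1L) * nr, "+")
          inD <- dd <= rD^2 & matrix(lin %in% pxSearch, length(iD))
          if (sum(inD) < 6L) next
          diskFlux <- sum(work[iD, jD][inD]) - bg * sum(inD)
          if (diskFlux < 4 * noiseRaw * sqrt(sum(inD))) next
          fits[[length(fits) + 1L]] <<- f
          work <<- subtractComp(work, f)
        }
      }
    }
    fitSequential(cand, strong)
    if (!length(fits)) next
    # residual pass: re-scan the subtracted image for shoulder peaks
    # hidden next to a brighter neighbour
    iBox <- pmin(pmax(range(pi0) + c(-20L, 20L), 1L), nr)
    jBox <- pmin(pmax(range(pj0) + c(-20L, 20L), 1L), ncol(work))
    enhR <- enhanceFoci(work[iBox[1]:iBox[2], jBox[1]:jBox[2]],
                        sigma1 = psfSigmaPx)
    isMaxR <- localMax3x3(enhR)
    ciS <- ((pxSearch - 1L) %% nr) + 1L - (iBox[1] - 1L)
    cjS <- ((pxSearch - 1L) %/% nr) + 1L - (jBox[1] - 1L)
    okS <- ciS >= 1L & ciS <= nrow(enhR) & cjS >= 1L & cjS <= ncol(enhR)
    subIdx <- (cjS[okS] - 1L) * nrow(enhR) + ciS[okS]
    cand2 <- pxSearch[okS][isMaxR[subIdx] &
                             enhR[subIdx] > (minPeakSnr + 1) * noiseEnhBg &
                             work[pxSearch[okS]] - bg > minPeakSnr * noiseRaw]
    cand2 <- setdiff(cand2, cand)
    if (length(cand2)) {
      cand <- cand2
      ci <- ((cand - 1L) %% nr) + 1L
      cj <- ((cand - 1L) %/% nr) + 1L
      fitSequential(cand, rep(TRUE, length(cand)))
    }
    # merge peaks closer than one PSF sigma (keep the brighter)
    ord <- order(vapply(fits, `[[`, numeric(1), "integrated"),
                 decreasing = TRUE)
    kept <- list()
    for (q in ord) {
      f <- fits[[q]]
      tooClose <- any(vapply(kept, function(g)
        (g$xUm - f$xUm)^2 + (g$yUm - f$yUm)^2 <
          (psfSigmaPx * pixelSize)^2, logical(1)))
      # wing suppression: a much dimmer peak inside 3 sigma of an accepted
      # focus is fit residue, not a separate binding site
      inWing <- any(vapply(kept, function(g)
        (g$xUm - f$xUm)^2 + (g$yUm - f$yUm)^2 <
          (3 * psfSigmaPx * pixelSize)^2 &&
          f$integrated < 0.25 * g$integrated, logical(1)))
      if (!tooClose && !inWing) kept[[length(kept) + 1L]] <- f
    }
    for (f in kept) {
      # accept centroids within half a pixel of the outline (membrane
      # foci localize onto the boundary within noise)
      tolUm <- pixelSize / 2
      nearPoly <- any(pointsInPolygon(
        cell@vertices,
        f$xUm + c(0, tolUm, -tolUm, 0, 0),
        f$yUm + c(0, 0, 0, tolUm, -tolUm)))
      if (!nearPoly) next
      rec[[length(rec) + 1L]] <- data.frame(
        cell_id = cell@cellId, channel = channel, time_point = timePoint,
        x_px = f$xUm / pixelSize, y_px = f$yUm / pixelSize,
        x_um = f$xUm, y_um = f$yUm,
        intensity = f$integrated, snr = f$amp / noiseRaw,
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rec)) do.call(rbind, rec) else data.frame(
    cell_id = character(0), channel = character(0), time_point = numeric(0),
    x_px = numeric(0), y_px = numeric(0), x_um = numeric(0),
    y_um = numeric(0), intensity = numeric(0), snr = numeric(0),
    stringsAsFactors = FALSE)
  methods::new("FocusSet", records = records, pixelSize = pixelSize)
}

#' Per-cell focus statistics
#'
#' Counts foci per cell, computes the focus density (foci per cell area),
#' mean cell intensity (mean counts per pixel inside the outline, camera
#' offset subtracted) and cell length, plus an ensemble summary (mean and
#' SEM of foci per cell, mean length). The camera offset defaults to the
#' median of all pixels outside every outline.
#'
#' @param fociSet a [FocusSet-class] (detected or ground truth).
#' @param cells a [CellSet-class]; every focus must reference one of these
#'   cells.
#' @param image optional 2D matrix for mean-intensity measurements.
#' @param offset camera offset in counts; estimated from off-cell pixels
#'   when NULL and an image is given.
#' @param pixelSize um per pixel.
#' @return list with \code{perCell} (data.frame) and \code{summary}
#'   (data.frame with mean, SEM, n).
#' @export
perCellStats <- function(fociSet, cells, image = NULL, offset = NULL,
                         pixelSize = 0.1) {
  stopifnot(is(cells, "CellSet"))
  recs <- if (is(fociSet, "FocusSet")) foci(fociSet) else fociSet
  ids <- vapply(cells@cells, cellId, character(1))
  unknown <- setdiff(unique(recs$cell_id), ids)
  stopIfNot(length(unknown) == 0,
            paste("focus records reference unknown cells:",
                  paste(unknown, collapse = ", ")))
  if (!is.null(image) && is.null(offset)) {
    occupied <- unique(unlist(lapply(cells@cells, pixelsInsideCell,
                                     dim = dim(image),
                                     pixelSize = pixelSize)))
    off <- setdiff(seq_along(image), occupied)
    offset <- if (length(off)) stats::median(image[off]) else 0
  }
  perCell <- do.call(rbind, lapply(cells@cells, function(cell) {
    nf <- sum(recs$cell_id == cell@cellId)
    mci <- NA_real_
    if (!is.null(image)) {
      px <- pixelsInsideCell(cell, dim(image), pixelSize)
      if (length(px)) mci <- mean(image[px]) - offset
    }
    data.frame(cell_id = cell@cellId, time_point = cell@timePoint,
               n_foci = nf, area_um2 = cell@area,
               focus_density = nf / cell@area,
               mean_cell_intensity = mci, length_um = cell@length,
               volume_fl = cell@volume, stringsAsFactors = FALSE)
  }))
  summary <- data.frame(
    mean_foci_per_cell = mean(perCell$n_foci),
    sem_foci_per_cell = stats::sd(perCell$n_foci) / sqrt(nrow(perCell)),
    mean_length_um = mean(perCell$length_um),
    mean_density = mean(perCell$focus_density),
    n_cells = nrow(perCell))
  list(perCell = perCell, summary = summary)
}
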