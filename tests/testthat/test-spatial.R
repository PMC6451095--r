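test_that("width coordinates measure signed distance from the centre spline", {
  cl <- generateCell(4, 1, centre = c(5, 5), theta = 0.4)
  # points constructed on the spline and at the membrane
  onSpline <- FociTrace:::cellLocalToGlobal(cl, c(-1, 0, 1), c(0, 0, 0))
  w <- widthCoordinate(onSpline[, "x"], onSpline[, "y"], cl)
  expect_equal(w, c(0, 0, 0), tolerance = 1e-9)

  nearMembrane <- FociTrace:::cellLocalToGlobal(cl, c(0, 0),
                                                c(0.495, -0.495))
  w2 <- widthCoordinate(nearMembrane[, "x"], nearMembrane[, "y"], cl)
  expect_equal(w2, c(0.495, -0.495), tolerance = 1e-9)

  expect_error(widthCoordinate(20, 20, cl), "outside")

  # placement ground truth is reproduced exactly for rotated cells
  f <- placeFoci(cl, 200, "peripheral", seed = 3)
  expect_equal(widthCoordinate(f$x_um, f$y_um, cl), f$width_um,
               tolerance = 1e-9)
})

test_that("width histograms are symmetric, conservative and mode-faithful", {
  expect_equal(widthHistogram(numeric(0))@nFoci, 0L)
  expect_error(widthHistogram(c(0.1), binWidth = 0), "binWidth")

  cl <- generateCell(3, 1)
  peri <- placeFoci(cl, 1000, "peripheral", seed = 7)
  wp <- widthHistogram(peri$width_um, binWidth = 0.1)
  expect_equal(sum(wp@counts), 1000L)
  neg <- wp@mids < 0; pos <- wp@mids > 0
  expect_equal(wp@mids[neg][which.max(wp@counts[neg])], -0.3)
  expect_equal(wp@mids[pos][which.max(wp@counts[pos])], 0.3)

  central <- placeFoci(cl, 1000, "central", seed = 8)
  wc <- widthHistogram(central$width_um, binWidth = 0.1)
  expect_equal(wc@mids[which.max(wc@counts)], 0)
  expect_gte(mean(abs(central$width_um) <= 0.2), 0.9)

  # sign flip mirrors the histogram exactly
  flipped <- widthHistogram(-peri$width_um, binWidth = 0.1,
                            halfRange = max(abs(peri$width_um)) + 0.1)
  ref <- widthHistogram(peri$width_um, binWidth = 0.1,
                        halfRange = max(abs(peri$width_um)) + 0.1)
  expect_equal(flipped@counts, rev(ref@counts))

  # uniform-mode profiles are mirror-symmetric (two-sample test between
  # the folded halves)
  unif <- placeFoci(cl, 1000, "uniform", seed = 9)
  w <- unif$width_um
  p <- suppressWarnings(stats::ks.test(w[w > 0], -w[w < 0]))$p.value
  expect_gt(p, 0.01)
})

test_that("the band-pass filter keeps foci and suppresses smooth signal", {
  expect_true(all(enhanceFoci(matrix(5, 64, 64)) < 1e-9))

  # rendered focus: the enhanced peak stays within half a pixel
  fx <- singleCellField()
  f <- data.frame(cell_id = "cell_1", channel = "A", time_point = 0,
                  x_um = 3.04, y_um = 1.97, n_molecules = 1L)
  img <- renderFrame(fx$set, f, frameSizePx = 64L, freeCopies = 0,
                     autofluorescenceEquiv = 0, noise = FALSE, offset = 0)
  e <- enhanceFoci(img)
  peak <- which(e == max(e), arr.ind = TRUE)
  expect_lt(abs((peak[1, "col"] - 0.5) * 0.1 - 3.04), 0.05)
  expect_lt(abs((peak[1, "row"] - 0.5) * 0.1 - 1.97), 0.05)

  # a linear gradient is suppressed below 5% of a focus peak (away from
  # the frame border, where any finite filter rings)
  grad <- outer(seq(0, 20, length.out = 128), rep(1, 128))
  eg <- enhanceFoci(grad)
  expect_lt(max(eg[30:98, 30:98]), 0.05 * max(e))
})

test_that("line-scan contours track the spatial mode over time", {
  cfg <- timelapseConfig(
    nCells = 12L, duration = 60, interval = 30, seed = 8, channels = "B",
    focusDensity = c(B = 0.8),
    stoichiometrySchedule = list(B = list(before = 1L, after = 1L,
                                          switchTime = Inf)),
    spatialMode = list(B = list(before = "central", after = "peripheral",
                                switchTime = 30)))
  tl <- generateTimelapse(cfg)
  imgs <- lapply(seq_along(tl@cells), function(ti)
    tl@frames[[1]][[ti]][["B"]])
  lc <- linescanContour(imgs, tl@cells, seq(0, 60, 30))
  m <- lc@matrix
  m[!is.finite(m)] <- 0
  peakAt <- vapply(seq_len(nrow(m)), function(r)
    abs(lc@widthAxis[which.max(m[r, ])]), numeric(1))
  # central ridge before the switch, split ridge near +/- 0.3 um after
  expect_lte(peakAt[1], 0.1)
  expect_true(all(peakAt[2:3] >= 0.2 & peakAt[2:3] <= 0.4))

  # all-zero images give an all-zero contour
  zeros <- lapply(imgs, function(x) x * 0)
  lc0 <- linescanContour(zeros, tl@cells, seq(0, 60, 30))
  expect_true(all(abs(lc0@matrix) < 1e-9, na.rm = TRUE))

  # contour row sums scale with the total enhanced intensity per time
  rowTotals <- rowSums(m)
  enhTotals <- vapply(imgs, function(x) sum(enhanceFoci(x)), numeric(1))
  ratio <- rowTotals / enhTotals
  expect_lt(stats::sd(ratio) / mean(ratio), 0.5)
})
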