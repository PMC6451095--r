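test_that("mask segmentation recovers rod outlines and drops border cells", {
  expect_length(segmentCells(matrix(0, 64, 64)), 0)

  mask <- matrix(0, 128, 128)
  truth <- list(generateCell(3, 1, "a", centre = c(3, 3)),
                generateCell(4, 1.1, "b", centre = c(8, 8), theta = 0.5),
                generateCell(2.5, 0.9, "c", centre = c(3, 9)))
  for (cc in truth) {
    px <- FociTrace:::pixelsInsideCell(cc, c(128, 128), 0.1)
    mask[px] <- 1
  }
  seg <- segmentCells(mask, pixelSize = 0.1)
  expect_length(seg, 3)
  segAreas <- sort(cellTable(seg)$area_um2)
  trueAreas <- sort(vapply(truth, cellArea, numeric(1)))
  expect_equal(segAreas, trueAreas, tolerance = 0.05)

  # a cell touching the frame border is discarded
  border <- matrix(0, 64, 64)
  border[1:10, 20:40] <- 1
  expect_length(segmentCells(border), 0)
})

test_that("flat images yield no foci and bad thresholds error", {
  fx <- singleCellField()
  flat <- matrix(100, 64, 64)
  expect_length(detectFoci(flat, fx$set), 0)
  expect_error(detectFoci(flat, fx$set, minPeakSnr = 0), "minPeakSnr")
})

test_that("isolated rendered foci are recovered once with sub-pixel accuracy", {
  fx <- singleCellField()
  nSingle <- 0; errs <- numeric(0)
  for (s in 1:40) {
    f <- placeFoci(fx$cell, 1, "uniform", seed = s)
    img <- renderFrame(fx$set, f, frameSizePx = 64L, freeCopies = 16,
                       autofluorescenceEquiv = 2.5, seed = s + 1000)
    d <- foci(suppressWarnings(detectFoci(img, fx$set)))
    if (nrow(d) == 1) {
      err <- sqrt((d$x_um - f$x_um)^2 + (d$y_um - f$y_um)^2)
      if (err <= 0.1) nSingle <- nSingle + 1
      errs <- c(errs, err)
    }
  }
  expect_gte(nSingle / 40, 0.9)
  expect_lt(stats::median(errs) / 0.1, 0.5)  # px
})

test_that("two foci five pixels apart give two records", {
  fx <- singleCellField(length = 3.4)
  f <- data.frame(cell_id = "cell_1", channel = "A", time_point = 0,
                  x_um = c(2.75, 3.25), y_um = c(2, 2), n_molecules = 1L)
  hits <- 0
  for (s in 1:10) {
    img <- renderFrame(fx$set, f, frameSizePx = 64L, freeCopies = 16,
                       autofluorescenceEquiv = 2.5, seed = s)
    d <- foci(suppressWarnings(detectFoci(img, fx$set)))
    hits <- hits + (nrow(d) == 2)
  }
  expect_gte(hits, 9)
})

test_that("per-cell statistics count, normalize and summarize correctly", {
  cl1 <- generateCell(3, 1, "c1", centre = c(3, 2))
  cl2 <- generateCell(4, 1, "c2", centre = c(3, 5))
  cset <- methods::new("CellSet", cells = list(cl1, cl2))
  recs <- rbind(placeFoci(cl1, 3, "uniform", seed = 1),
                placeFoci(cl2, 1, "uniform", seed = 2))
  fs <- methods::new("FocusSet", records = recs, pixelSize = 0.1)
  st <- perCellStats(fs, cset)
  expect_equal(st$perCell$n_foci, c(3, 1))
  expect_equal(st$perCell$focus_density,
               st$perCell$n_foci / st$perCell$area_um2)
  expect_equal(st$summary$mean_foci_per_cell, 2)
  expect_equal(st$summary$n_cells, 2)

  # zero foci: all counts and densities zero
  empty <- methods::new("FocusSet", records = recs[0, ], pixelSize = 0.1)
  st0 <- perCellStats(empty, cset)
  expect_true(all(st0$perCell$n_foci == 0))
  expect_true(all(st0$perCell$focus_density == 0))

  # unknown cell reference is a consistency error
  badRecs <- recs
  badRecs$cell_id[1] <- "ghost"
  bad <- methods::new("FocusSet", records = badRecs, pixelSize = 0.1)
  expect_error(perCellStats(bad, cset), "unknown cells")
})

test_that("a focus-density ensemble is recovered by detection within 10%", {
  # density tuned so that cells average ~2.2 foci per ~2.8 um^2 cell
  cfg <- uniformTimelapseConfig(60L, seed = 77)
  tl <- generateTimelapse(cfg)
  gt <- foci(tl)
  gt0 <- gt[gt$time_point == 0, ]
  det <- detectAllFields(tl)
  det0 <- det[det$time_point == 0, ]
  nCells <- cfg@nCells
  expect_equal(nrow(det0) / nCells, nrow(gt0) / nCells, tolerance = 0.1)
})

test_that("mean cell intensity is time-invariant at constant concentration", {
  cfg <- timelapseConfig(nCells = 12L, duration = 60, interval = 30,
                         seed = 13, channels = "A",
                         focusDensity = c(A = 0.79))
  tl <- generateTimelapse(cfg)
  means <- vapply(seq_along(tl@cells), function(ti) {
    st <- perCellStats(
      methods::new("FocusSet", records = foci(tl)[0, ], pixelSize = 0.1),
      tl@cells[[ti]], image = tl@frames[[1]][[ti]][["A"]],
      pixelSize = 0.1)
    mean(st$perCell$mean_cell_intensity)
  }, numeric(1))
  expect_lt(max(abs(means / means[1] - 1)), 0.05)
})
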