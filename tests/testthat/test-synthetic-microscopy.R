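test_that("spherocylinder outlines have exact closed-form area and volume", {
  cl <- generateCell(3, 1)
  expect_equal(cellArea(cl), 2.785398, tolerance = 1e-6)
  expect_equal(cellVolume(cl), 2.094395, tolerance = 1e-6)
  # polygon shoelace area agrees with the closed form within 2%
  expect_equal(FociTrace:::polygonArea(cellVertices(cl)), cellArea(cl),
               tolerance = 0.02)
  # degenerate geometry rejected
  expect_error(generateCell(0.5, 1), "length >= width")
  # polygon is explicitly closed
  v <- cellVertices(cl)
  expect_equal(v[1, ], v[nrow(v), ])
})

test_that("focus placement respects the short-axis mode geometry", {
  cl <- generateCell(3, 1)
  expect_equal(nrow(placeFoci(cl, 0)), 0L)
  expect_error(placeFoci(cl, 5, mode = "sideways"))

  central <- placeFoci(cl, 1000, "central", seed = 11)
  expect_gte(mean(abs(central$width_um) <= 0.2), 0.9)

  peri <- placeFoci(cl, 1000, "peripheral", seed = 12)
  wp <- widthHistogram(peri$width_um, binWidth = 0.1)
  # modes of the bimodal histogram sit in the -0.3 and +0.3 um bins
  neg <- wp@counts[wp@mids < 0]
  pos <- wp@counts[wp@mids > 0]
  expect_equal(wp@mids[wp@mids < 0][which.max(neg)], -0.3)
  expect_equal(wp@mids[wp@mids > 0][which.max(pos)], 0.3)

  # every placement (all modes) falls inside the polygon
  for (mode in c("uniform", "central", "peripheral")) {
    f <- placeFoci(cl, 300, mode, seed = 13)
    expect_true(all(FociTrace:::pointsInPolygon(cellVertices(cl),
                                                f$x_um, f$y_um)))
  }
})

test_that("rendered frames carry the configured focus flux and camera model", {
  fx <- singleCellField()
  f <- data.frame(cell_id = "cell_1", channel = "A", time_point = 0,
                  x_um = 3.02, y_um = 2.03, n_molecules = 1L)
  # noise-free integral of an isolated spot equals the per-molecule unit
  img <- renderFrame(fx$set, f, frameSizePx = 64L, freeCopies = 0,
                     autofluorescenceEquiv = 0, noise = FALSE, offset = 0)
  expect_equal(sum(img), 100, tolerance = 0.05)

  # empty frame is offset plus noise
  blank <- renderFrame(methods::new("CellSet", cells = list()),
                       f[0, ], frameSizePx = 32L, offset = 100, seed = 3)
  expect_equal(mean(blank), 100, tolerance = 0.05)

  # a focus outside every outline is a consistency error
  bad <- f; bad$x_um <- 10
  expect_error(renderFrame(fx$set, bad, frameSizePx = 64L),
               "inside a cell outline")

  # identical seeds give bit-identical frames
  a <- renderFrame(fx$set, f, frameSizePx = 64L, seed = 7)
  b <- renderFrame(fx$set, f, frameSizePx = 64L, seed = 7)
  expect_identical(a, b)
})

test_that("time-lapse ground truth obeys growth, density and dimer schedules", {
  cfg <- timelapseConfig(nCells = 60L, duration = 40, interval = 10,
                         seed = 21)
  tl <- generateTimelapse(cfg, render = FALSE)
  ct <- tl@cellTable
  gt <- foci(tl)

  # lengths constant before the filamentation onset, growing after
  len0 <- ct$length_um[ct$time_point == 0]
  len30 <- ct$length_um[ct$time_point == 30]
  len40 <- ct$length_um[ct$time_point == 40]
  expect_equal(len30, len0)
  expect_true(all(len40 > len0))

  # zero growth keeps lengths constant at all times
  cfg0 <- timelapseConfig(nCells = 10L, duration = 40, interval = 10,
                          growthRate = 0, seed = 3)
  tl0 <- generateTimelapse(cfg0, render = FALSE)
  lens <- tapply(tl0@cellTable$length_um, tl0@cellTable$cell_id,
                 function(x) diff(range(x)))
  expect_true(all(lens == 0))

  # channel-A stoichiometry doubles at the 30-min switch
  gA <- gt[gt$channel == "A", ]
  expect_equal(unique(gA$n_molecules[gA$time_point < 30]), 1L)
  expect_equal(unique(gA$n_molecules[gA$time_point >= 30]), 2L)

  # every ground-truth focus lies inside its cell polygon
  for (ti in seq_along(tl@cells)) {
    cs <- tl@cells[[ti]]
    ids <- vapply(cs@cells, cellId, character(1))
    gti <- gt[gt$time_point == cs[[1]]@timePoint, ]
    ok <- vapply(seq_len(nrow(gti)), function(k) {
      cell <- cs[[match(gti$cell_id[k], ids)]]
      FociTrace:::pointsInPolygon(cellVertices(cell), gti$x_um[k],
                                  gti$y_um[k])
    }, logical(1))
    expect_true(all(ok))
  }

  # duration below the interval is rejected
  expect_error(timelapseConfig(duration = 5, interval = 10), "duration")
})

test_that("ground-truth foci counts scale with cell area at fixed density", {
  cfg <- timelapseConfig(nCells = 80L, duration = 60, interval = 20,
                         seed = 31)
  tl <- generateTimelapse(cfg, render = FALSE)
  ct <- tl@cellTable
  gt <- foci(tl)
  gA <- gt[gt$channel == "A", ]
  key <- paste(ct$cell_id, ct$time_point)
  counts <- vapply(key, function(k) {
    parts <- strsplit(k, " ")[[1]]
    sum(gA$cell_id == parts[1] & gA$time_point == as.numeric(parts[2]))
  }, numeric(1))
  expect_gte(length(counts), 200)
  fit <- stats::lm(counts ~ ct$area_um2)
  expect_equal(unname(stats::coef(fit)[2]), 0.79, tolerance = 0.1)
  expect_lt(abs(unname(stats::coef(fit)[1])), 0.35)
})

test_that("generator output is bit-identical under an identical config", {
  cfg <- timelapseConfig(nCells = 8L, duration = 10, interval = 10,
                         seed = 99, frameSizePx = 256L)
  t1 <- generateTimelapse(cfg)
  t2 <- generateTimelapse(cfg)
  expect_identical(t1@frames, t2@frames)
  expect_identical(foci(t1), foci(t2))
  expect_identical(t1@cellTable, t2@cellTable)
})

test_that("the replication-shutdown preset loses foci after damage", {
  cfg <- timelapsePreset("replicationShutdown", nCells = 60L,
                         duration = 90, interval = 30, seed = 41,
                         growthRate = 0)
  tl <- generateTimelapse(cfg, render = FALSE)
  gt <- foci(tl)
  gA <- gt[gt$channel == "A", ]
  n0 <- sum(gA$time_point == 0)
  n90 <- sum(gA$time_point == 90)
  # density decays by exp(-0.025 * 90) ~ 0.11 of the initial value
  expect_lt(n90, 0.4 * n0)
})
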