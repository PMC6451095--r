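makeFocusTable <- function(x, y, cellId = "c1", channel = "A", tp = 0)
  data.frame(cell_id = cellId, channel = channel, time_point = tp,
             x_um = x, y_um = y, stringsAsFactors = FALSE)

test_that("directional matching honours the inclusive search radius", {
  a <- makeFocusTable(c(1, 2, 3), c(1, 1, 1))
  # identical coordinates colocalize fully in both directions
  res <- colocalize(a, makeFocusTable(c(1, 2, 3), c(1, 1, 1),
                                      channel = "B"))
  expect_equal(res$summary$pct_A_with_B, 100)
  expect_equal(res$summary$pct_B_with_A, 100)

  # a pair at exactly 218 nm matches; at 219 nm it does not
  at218 <- colocalize(makeFocusTable(1, 1),
                      makeFocusTable(1.218, 1, channel = "B"))
  expect_equal(at218$summary$pct_A_with_B, 100)
  at219 <- colocalize(makeFocusTable(1, 1),
                      makeFocusTable(1.219, 1, channel = "B"))
  expect_equal(at219$summary$pct_A_with_B, 0)

  # 3 of 10 query foci with a partner -> 30%
  a10 <- makeFocusTable(seq(1, 10), rep(1, 10))
  b <- makeFocusTable(c(1.05, 4.95, 8.1), c(1, 1, 1), channel = "B")
  expect_equal(colocalize(a10, b)$summary$pct_A_with_B, 30)

  # cross-cell pairs never match
  bOther <- makeFocusTable(1, 1, cellId = "c2", channel = "B")
  expect_equal(colocalize(makeFocusTable(1, 1),
                          bOther)$summary$pct_A_with_B, 0)

  # mixed time points are an input error
  aMix <- rbind(makeFocusTable(1, 1, tp = 0), makeFocusTable(2, 1, tp = 10))
  expect_error(colocalize(aMix, b), "time points")
})

test_that("matching is symmetric per pair and monotone in radius", {
  set.seed(4)
  a <- makeFocusTable(runif(30, 0, 5), runif(30, 0, 2))
  b <- makeFocusTable(runif(30, 0, 5), runif(30, 0, 2), channel = "B")
  res <- colocalize(a, b)
  # every matched (a, b) pair appears identically from both sides
  revRes <- colocalize(b, a)
  expect_equal(sort(res$pairs$distance_nm), sort(revRes$pairs$distance_nm))
  pcts <- vapply(c(100, 218, 400, 800), function(r)
    colocalize(a, b, radiusNm = r)$summary$pct_A_with_B, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("the analytic chance baseline matches geometry and Monte Carlo", {
  # one partner focus in a 3.73 um^2 cell covers pi * 0.218^2 / 3.73 ~ 4%
  cl <- generateCell(3.9446, 1)
  cs <- methods::new("CellSet", cells = list(cl))
  b1 <- placeFoci(cl, 1, "uniform", channel = "B", seed = 1)
  expect_equal(chanceColocalization(cs, b1), 4.0, tolerance = 0.01)
  expect_equal(chanceColocalization(cs, b1[0, ]), 0)

  # Monte-Carlo oracle: random query placements match the closed form
  # within 0.5 percentage points
  cells <- methods::new("CellSet", cells = lapply(1:10, function(k)
    generateCell(3.9446, 1, sprintf("c%02d", k), centre = c(4, 2.5 * k))))
  fB <- do.call(rbind, lapply(1:10, function(k)
    placeFoci(cells[[k]], 1, "uniform", channel = "B", seed = k)))
  analytic <- chanceColocalization(cells, fB)
  set.seed(11)
  nmc <- 10000; hits <- 0
  for (m in seq_len(nmc)) {
    k <- sample(10, 1)
    fa <- placeFoci(cells[[k]], 1, "uniform")
    bb <- fB[fB$cell_id == cellId(cells[[k]]), ]
    hits <- hits + any(sqrt((bb$x_um - fa$x_um)^2 +
                              (bb$y_um - fa$y_um)^2) <= 0.218)
  }
  expect_lt(abs(analytic - 100 * hits / nmc), 0.5)
})

test_that("area-shell histograms have equal-area bins and flat nulls", {
  h <- areaShellHistogram(c(50, 120, 200), 218, 4)
  expect_equal(h$upper_nm, 218 * sqrt(1:4 / 4), tolerance = 1e-9)
  expect_equal(sum(h$count), 3)
  expect_equal(areaShellHistogram(numeric(0), 218, 5)$count, rep(0L, 5))
  expect_error(areaShellHistogram(c(1, 2), 218, 0), "nBins")
  expect_error(areaShellHistogram(c(-1), 218, 4), "distances")

  # uniform scatter around reference points fills every annulus equally
  set.seed(21)
  n <- 10000
  r <- 218 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  d <- sqrt((r * cos(th))^2 + (r * sin(th))^2)
  hh <- areaShellHistogram(d, 218, 10)
  expect_gt(stats::chisq.test(hh$count)$p.value, 0.01)
})

test_that("time courses recover forced co-placement above chance", {
  cfg <- timelapseConfig(nCells = 80L, duration = 30, interval = 10,
                         seed = 61, coPlacement = 0.25)
  tl <- generateTimelapse(cfg, render = FALSE)
  gt <- foci(tl)
  tc <- colocalizationTimecourse(gt[gt$channel == "A", ],
                                 gt[gt$channel == "B", ],
                                 cellsByTime = tl@cells)
  expect_equal(nrow(tc), 4)
  # pooled over time points: forced fraction plus chance for the rest
  pooled <- sum(tc$pct_A_with_B * tc$n_A) / sum(tc$n_A)
  chance <- mean(tc$chance_pct_A_with_B)
  expect_equal(pooled - chance * 0.75, 25, tolerance = 5)

  # independent placements sit at the chance baseline
  cfg0 <- timelapseConfig(nCells = 80L, duration = 30, interval = 10,
                          seed = 62, coPlacement = 0)
  tl0 <- generateTimelapse(cfg0, render = FALSE)
  gt0 <- foci(tl0)
  tc0 <- colocalizationTimecourse(gt0[gt0$channel == "A", ],
                                  gt0[gt0$channel == "B", ],
                                  cellsByTime = tl0@cells)
  pooled0 <- sum(tc0$pct_A_with_B * tc0$n_A) / sum(tc0$n_A)
  expect_equal(pooled0, mean(tc0$chance_pct_A_with_B), tolerance = 2.5)

  # a time point missing one channel is skipped with a warning
  gA <- gt[gt$channel == "A", ]
  gB <- gt[gt$channel == "B" & gt$time_point != 10, ]
  expect_warning(tcSkip <- colocalizationTimecourse(gA, gB),
                 "missing a channel")
  expect_false(10 %in% tcSkip$time_point)
})
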