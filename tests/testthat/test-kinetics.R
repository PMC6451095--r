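test_that("normalized ACFs start at one and vanish for white noise", {
  set.seed(2)
  x <- rnorm(3000)
  cv <- autocorrelation(x, dt = 0.034)
  expect_equal(acfValues(cv)[1], 1)
  expect_lt(max(abs(acfValues(cv)[-1])), 4 / sqrt(length(x)))
  expect_error(autocorrelation(rep(1, 100)), "zero variance")
  expect_error(autocorrelation(c(1, 2)), "at least 10")
})

test_that("telegraph ACFs match the closed form exp(-(kOn+kOff) tau)", {
  kOn <- 0.5; kOff <- 0.5; dt <- 0.034
  nFrames <- 4000
  curves <- lapply(1:150, function(j)
    autocorrelation(simulateStateTrajectory(kOn, kOff, nFrames, dt,
                                            seed = j),
                    dt = dt, lagMax = 50))
  mc <- meanAcf(curves)
  expected <- telegraphAcfOracle(kOn + kOff, acfLags(mc), dt, nFrames)
  z <- (acfValues(mc) - expected)[-1] / acfSem(mc)[-1]
  expect_lt(mean(abs(z)), 1)
  expect_true(all(abs(z) < 3))
})

test_that("mean ACFs average per lag with shrinking SEM", {
  cv <- autocorrelation(rnorm(500), dt = 0.034)
  m <- meanAcf(list(cv, cv, cv))
  expect_equal(acfValues(m), acfValues(cv))
  expect_true(all(acfSem(m) == 0))
  expect_error(meanAcf(list(cv)), "at least 2")
  other <- autocorrelation(rnorm(200), dt = 0.034)
  expect_error(meanAcf(list(cv, other)), "lag grid")

  set.seed(3)
  curves <- lapply(1:64, function(j) autocorrelation(rnorm(300), dt = 0.034))
  semFew <- mean(acfSem(meanAcf(curves[1:16]))[-1])
  semMany <- mean(acfSem(meanAcf(curves))[-1])
  expect_equal(semFew / semMany, 2, tolerance = 0.35)
})

test_that("the exponential decomposition recovers known mixtures", {
  lags <- seq(0, 5, by = 0.034)

  # double-exponential mixture with 53% sub-frame amplitude
  y <- 0.12 * exp(-lags / 0.3) + 0.35 * exp(-lags / 1.5)
  y[1] <- 1
  set.seed(9)
  cv <- methods::new("AcfCurve", lags = lags,
                     values = y + rnorm(length(y), 0, 0.01),
                     sem = numeric(0), nTrajectories = 150L)
  fit <- fitAcfDecomposition(cv)
  expect_equal(fit@model, "double")
  expect_equal(fit@aS, 0.53, tolerance = 0.03)
  expect_equal(fit@aM, 0.12, tolerance = 0.15 * 0.12 / 0.12)
  expect_equal(fit@tauM, 0.3, tolerance = 0.15)
  expect_equal(fit@aL, 0.35, tolerance = 0.15)
  expect_equal(fit@tauL, 1.5, tolerance = 0.15)
  expect_equal(fit@aS + fit@aM + fit@aL, 1, tolerance = 1e-9)

  # noiseless single exponential selects the single model
  y2 <- 0.5 * exp(-lags / 2.2); y2[1] <- 1
  cv2 <- methods::new("AcfCurve", lags = lags, values = y2,
                      sem = numeric(0), nTrajectories = 10L)
  fit2 <- fitAcfDecomposition(cv2)
  expect_equal(fit2@model, "single")
  expect_equal(fit2@tauL, 2.2, tolerance = 0.01)
  expect_equal(fit2@aS, 0.5, tolerance = 0.01)

  # zero correlation beyond lag zero is the degenerate pure-noise case
  y3 <- c(1, rep(0, length(lags) - 1))
  cv3 <- methods::new("AcfCurve", lags = lags, values = y3,
                      sem = numeric(0), nTrajectories = 10L)
  fit3 <- fitAcfDecomposition(cv3)
  expect_equal(fit3@model, "degenerate")
  expect_equal(fit3@aS, 1)
})

test_that("simulated complex kinetics set the fitted dominant timescale", {
  kOn <- 0.3; kOff <- 0.7   # ACF timescale 1 s
  # trajectories much longer than the correlation time, so the finite-
  # length truncation of the ACF estimator does not shorten the fit
  cfg <- simulationConfig(kOnComplex = kOn, kOffComplex = kOff,
                          tauBleach = 1e6, snr = 20, nFrames = 2000L,
                          seed = 23)
  ts <- simulateTrajectories(cfg, 100)
  curves <- suppressMessages(autocorrelation(ts))
  fit <- fitAcfDecomposition(meanAcf(curves))
  expect_equal(fit@tauL, 1 / (kOn + kOff), tolerance = 0.2)
})

test_that("trajectory extraction integrates a disk over the stack", {
  # constant stack: background-subtracted signal is identically zero
  stack <- array(7, c(40, 40, 20))
  tr <- extractTrajectory(stack, c(2, 2), roiRadiusPx = 3)
  expect_equal(dim(tr), c(20L, 1L))
  expect_true(all(abs(intensities(tr)) < 1e-9))
  expect_equal(frameTime(tr), 0.034)
  expect_error(extractTrajectory(stack, c(0.2, 0.2), roiRadiusPx = 4),
               "exceeds the frame")

  # a rendered focus movie returns its integrated intensity per frame
  fx <- singleCellField()
  f <- data.frame(cell_id = "cell_1", channel = "A", time_point = 0,
                  x_um = 3, y_um = 2, n_molecules = 2L)
  img <- renderFrame(fx$set, f, frameSizePx = 64L, freeCopies = 10,
                     autofluorescenceEquiv = 2.5, noise = FALSE)
  stack <- array(img, c(64, 64, 5))
  tr <- extractTrajectory(stack, c(3, 2), roiRadiusPx = 4, cell = fx$cell)
  expect_equal(mean(intensities(tr)), 200, tolerance = 0.1)
})
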