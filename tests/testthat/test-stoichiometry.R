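test_that("flat-field correction divides by the normalized profile", {
  img <- matrix(100, 32, 32)
  expect_equal(flattenField(img, matrix(1, 32, 32)), img)
  expect_error(flattenField(img, matrix(0, 32, 32)), "positive")
  expect_error(flattenField(img, matrix(1, 16, 16)), "shape")

  # a centre 12% brighter than the corners scales corners up by 1.12
  prof <- illuminationProfile(32, centreCornerRatio = 1.12)
  corr <- flattenField(img, prof)
  expect_equal(corr[1, 1] / 100, 1.12, tolerance = 1e-3)
  expect_equal(min(corr), 100, tolerance = 0.001)

  # round trip: imaging through the profile then flattening restores
  # the object
  obj <- matrix(stats::runif(32 * 32, 50, 150), 32)
  expect_equal(flattenField(obj * prof / max(prof), prof), obj,
               tolerance = 1e-9)
})

test_that("photobleaching step calibration finds the single-molecule unit", {
  # noiseless three-step staircase: unit exactly 100
  x <- c(rep(300, 20), rep(200, 20), rep(100, 20), rep(0, 20))
  u <- unitIntensityFromSteps(matrix(rep(x, 12), ncol = 12))
  expect_equal(u$unit, 100)

  # a constant trajectory has no steps: calibration error
  expect_error(unitIntensityFromSteps(matrix(5, 300, 12)),
               "calibration failed")

  # simulated bleaching ensembles at snr 3 recover the unit within 10%
  cfg <- simulationConfig(kOnComplex = 1, kOffComplex = 0, tauBleach = 2,
                          snr = 3, nMolPerComplex = 2L, seed = 5)
  u2 <- unitIntensityFromSteps(intensities(simulateTrajectories(cfg, 60)) * 100)
  expect_equal(u2$unit, 100, tolerance = 0.1)
})

test_that("copy-number arithmetic reproduces the worked conversions", {
  # 20.6 molecule-units of integrated signal minus 2.5 autofluorescence
  est <- copyNumber(20.6, areaPx = 100, unitIntensity = 100,
                    autofluorescenceEquiv = 2.5)
  expect_equal(est$n_molecules, 18.1, tolerance = 1e-9)

  # exactly the autofluorescence floor gives zero
  expect_equal(copyNumber(2.5, 100, 100, 2.5)$n_molecules, 0)

  # below the floor clamps to zero with a warning
  expect_warning(est0 <- copyNumber(1.0, 100, 100, 2.5), "clamped")
  expect_equal(est0$n_molecules, 0)
  expect_error(copyNumber(10, 100, unitIntensity = 0), "unitIntensity")
})

test_that("concentrations follow n / (V * N_A) in nanomolar", {
  expect_equal(moleculeConcentration(1, 1.66), 1, tolerance = 0.001)
  expect_equal(moleculeConcentration(0, 2), 0)
  expect_error(moleculeConcentration(1, 0), "volume")

  # homogeneity: scaling molecules and volume together is neutral
  expect_equal(moleculeConcentration(3 * 18.1, 3 * 5.57),
               moleculeConcentration(18.1, 5.57))

  # 18.1 molecules at 5.4 nM implies V ~ 5.57 fL; inverting returns 5.4
  v <- 18.1 / (5.4e-9 * 6.02214076e23 * 1e-15)
  expect_equal(moleculeConcentration(18.1, v), 5.4, tolerance = 1e-9)
})

test_that("molecules per focus round to the expected stoichiometry", {
  expect_equal(moleculesPerFocus(100, 100)$n_molecules, 1L)
  expect_equal(moleculesPerFocus(200, 100)$n_molecules, 2L)
  expect_equal(moleculesPerFocus(c(95, 210), 100)$ratio, c(0.95, 2.1))
  expect_error(moleculesPerFocus(-5, 100), "intensities")
  expect_error(moleculesPerFocus(100, 0), "unitIntensity")
})

test_that("bound fractions scale linearly in foci and stoichiometry", {
  expect_equal(boundFraction(2, 1, 18), 100 * 2 / 18)
  expect_equal(boundFraction(2, 2, 18), 100 * 4 / 18)
  expect_equal(boundFraction(0, 1, 18), 0)
  expect_error(boundFraction(2, 1, 0), "copiesPerCell")
  # doubling molecules per focus doubles the bound fraction exactly
  expect_equal(boundFraction(3, 2, 25) / boundFraction(3, 1, 25), 2)
})

test_that("dimer-mode foci double their intensity-derived stoichiometry", {
  cfg <- timelapseConfig(nCells = 15L, duration = 40, interval = 40,
                         seed = 55, channels = "A",
                         focusDensity = c(A = 0.5),
                         spatialMode = list(A = list(
                           before = "uniform", after = "uniform",
                           switchTime = Inf)))
  tl <- generateTimelapse(cfg)
  modal <- vapply(1:2, function(ti) {
    det <- detectAllFields(tl, timeIndex = ti)
    m <- moleculesPerFocus(det$intensity, 100)$n_molecules
    as.integer(names(sort(table(m), decreasing = TRUE))[1])
  }, integer(1))
  expect_equal(modal, c(1L, 2L))
})
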