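test_that("ionization line passes through the printed anchors with calibrated intercepts", {
  expect_equal(mean_ionizations("alpha", 162.4, CAL), 17.0)
  expect_equal(mean_ionizations("proton", 81.5, CAL), 9.4)
  expect_equal(mean_ionizations("electron", 28.7, CAL), 4.4)
  expect_equal(cal_value(CAL, "ion_intercept", "alpha"), 0.76, tolerance = 1e-6)
  expect_equal(cal_value(CAL, "ion_intercept", "proton"), 0.435, tolerance = 1e-6)
  expect_equal(cal_value(CAL, "ion_intercept", "electron"), 0.382, tolerance = 1e-6)
  expect_equal(mean_ionizations("electron", 0, CAL), 0.382, tolerance = 1e-6)
})

test_that("mean ionizations increase with LET and order electron > proton > alpha", {
  grid <- seq(0, 300, by = 0.5)
  for (p in c("electron", "proton", "alpha")) {
    expect_true(all(diff(mean_ionizations(p, grid, CAL)) > 0))
  }
  at <- seq(8.5, 28, by = 0.5) # electrons exist up to 28.7 keV/um
  expect_true(all(mean_ionizations("electron", at, CAL) >
                    mean_ionizations("proton", at, CAL)))
  # protons overtake alphas above roughly 27-33 keV/um (the anchored
  # intercepts put the crossover at ~32.5)
  above <- seq(35, 81.5, by = 0.5)
  expect_true(all(mean_ionizations("proton", above, CAL) >
                    mean_ionizations("alpha", above, CAL)))
  expect_error(mean_ionizations("alpha", 301, CAL), "outside")
})

test_that("Poisson sampling matches its mean and is seed-reproducible", {
  n <- 1e5
  draws <- sample_ionizations("alpha", 162.4, n = n, seed = 11, cal = CAL)
  expect_lt(abs(mean(draws) - 17.0), 3 * sqrt(17.0 / n))
  lo <- sample_ionizations("electron", 0, n = n, seed = 12, cal = CAL)
  expect_lt(abs(mean(lo) - 0.382), 3 * sqrt(0.382 / n))
  expect_identical(draws, sample_ionizations("alpha", 162.4, n = n, seed = 11, cal = CAL))
})

test_that("regression on sampled counts recovers the configured slopes", {
  fits <- ionization_slope_fit(n_draws = 2e4, seed = 21, cal = CAL)
  slopes <- cal_value(CAL, "ion_slope")[fits$particle]
  expect_true(all(abs(fits$slope - slopes) / slopes < 0.02))
  expect_true(all(fits$r_squared > 0.995))
})

test_that("LEE counts derive from the lesion calibration and grow with LET", {
  expect_equal(mean_lee_count("alpha", 162.4, CAL), 57.695, tolerance = 1e-4)
  # where the quadratic falls below the linear lesion term the count clamps to 0
  expect_equal(mean_lee_count("electron", 0.5, CAL), 0)
  expect_gt(mean_lee_count("alpha", 103.4, CAL), mean_lee_count("alpha", 15.2, CAL))
})

test_that("LEE spectrum has unit mass, bounded support and an 8-11 eV mode", {
  dens <- integrate(function(x) lee_spectrum_density(x, CAL), 1, 25,
                    subdivisions = 500L)
  expect_equal(dens$value, 1, tolerance = 1e-6)
  expect_identical(lee_spectrum_density(c(0.5, 25.5, 40), CAL), c(0, 0, 0))
  x <- sample_lee_spectrum(5e4, seed = 31, cal = CAL)
  expect_true(all(x >= 1 & x <= 25))
  h <- lee_spectrum_histogram(5e4, seed = 31, bin_width = 1, cal = CAL)
  modal <- h$bin_low_ev[which.max(h$fraction)]
  expect_gte(modal, 8); expect_lte(modal + 1, 11)
  expect_identical(sample_lee_spectrum(0, cal = CAL), numeric(0))
  expect_error(sample_lee_spectrum(-1, cal = CAL), "non-negative")
  expect_identical(x, sample_lee_spectrum(5e4, seed = 31, cal = CAL))
})
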