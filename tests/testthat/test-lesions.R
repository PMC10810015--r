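test_that("three-point quadratic calibration matches an independent regression oracle", {
  anchors <- data.frame(let = c(162.4, 103.4, 11.5), lesions = c(39.8, 23.1, 2.0))
  fit <- calibrate_lesion_model(anchors, particle = "alpha")
  # oracle: least squares through three points is the exact interpolant
  or <- lm(lesions ~ I(let^2) + let, anchors)
  expect_equal(unname(fit$coefficients),
               unname(c(coef(or)[2], coef(or)[3], coef(or)[1])), tolerance = 1e-9)
  set.seed(42)
  for (i in 1:5) {
    an <- data.frame(let = sort(runif(3, 1, 300)), lesions = runif(3, 0.5, 50))
    f <- calibrate_lesion_model(an)
    expect_equal(predict(f, an$let), pmax(0, an$lesions), tolerance = 1e-8)
  }
  expect_error(
    calibrate_lesion_model(data.frame(let = c(10, 10, 20), lesions = 1:3)),
    "distinct"
  )
  expect_equal(tidy(fit)$term, c("let^2", "let", "intercept"))
  expect_lt(glance(fit)$max_abs_residual, 1e-9)
})

test_that("built-in lesion quadratics reproduce their anchors and frozen coefficients", {
  expect_equal(unname(cal_value(CAL, "lambda_coef_alpha")),
               c(3.542310e-04, 0.18889625, -0.21915388), tolerance = 1e-6)
  expect_equal(unname(cal_value(CAL, "lambda_coef_proton")),
               c(1.209016e-03, 0.21456497, -0.12373936), tolerance = 1e-6)
  expect_equal(unname(cal_value(CAL, "lambda_coef_electron")),
               c(3.518166e-02, 3.052821e-02, 9.742178e-03), tolerance = 1e-6)
  # anchors exactly
  expect_equal(mean_lesions("alpha", c(162.4, 103.4, 11.5), CAL),
               c(39.8, 23.1, 2.0), tolerance = 1e-6)
  expect_equal(mean_lesions("proton", c(41.3, 26.1, 9.4), CAL),
               c(10.8, 6.3, 2.0), tolerance = 1e-6)
  expect_equal(mean_lesions("electron", 7.1, CAL), 2.0, tolerance = 1e-6)
  # published values not used as anchors are recovered within 10%
  expect_rel(mean_lesions("alpha", 15.2, CAL), 2.8, 0.10)
  expect_rel(mean_lesions("alpha", 8.6, CAL), 1.4, 0.10)
})

test_that("lesion means increase strictly over each calibrated range", {
  ranges <- list(alpha = c(1, 270), proton = c(0.7, 85), electron = c(0.2, 29))
  for (p in names(ranges)) {
    grid <- seq(ranges[[p]][1], ranges[[p]][2], length.out = 400)
    expect_true(all(diff(mean_lesions(p, grid, CAL)) > 0))
  }
})

test_that("mechanistic decomposition conserves the total and matches hand arithmetic", {
  d <- decompose_lesions("alpha", 162.4, CAL)
  expect_equal(d$direct_linear + d$indirect_linear, 12.494, tolerance = 1e-3)
  expect_equal(d$lee, 27.306, tolerance = 1e-3)
  expect_equal(d$ssb_mean, 20.913, tolerance = 1e-3)
  expect_equal(d$ssb_mean + d$base_mean, d$total)
  z <- decompose_lesions("proton", 0, CAL)
  expect_true(all(unlist(z[, 3:8]) == 0))
  set.seed(7)
  for (p in c("electron", "proton", "alpha")) {
    lets <- runif(20, 0.5, 250)
    d <- decompose_lesions(p, lets, CAL)
    expect_equal(d$direct_linear + d$indirect_linear + d$lee, d$total,
                 tolerance = 1e-10)
    expect_true(all(d$lee >= 0) && all(d$base_mean >= -1e-12))
  }
})

test_that("direct-type lesion share grows towards high LET", {
  for (p in c("proton", "alpha")) {
    grid <- seq(10, 250, by = 5)
    d <- decompose_lesions(p, grid, CAL)
    share <- (d$direct_linear + d$lee) / d$total
    expect_true(all(diff(share) > 0))
  }
  d <- decompose_lesions("electron", c(0.2, 29), CAL)
  share <- (d$direct_linear + d$lee) / d$total
  expect_gt(share[2], share[1])
})

test_that("DSB model is anchored at one DSB at each printed minimum LET and capped", {
  expect_equal(mean_dsb("electron", 9.0, CAL), 1.0, tolerance = 1e-6)
  expect_equal(mean_dsb("proton", 11.8, CAL), 1.0, tolerance = 1e-6)
  expect_equal(mean_dsb("alpha", 15.2, CAL), 1.0, tolerance = 1e-6)
  expect_equal(mean_dsb("alpha", 0, CAL), 0)
  # at high LET the lambda/2 cap is active
  expect_equal(mean_dsb("alpha", 162.4, CAL), 19.9)
  expect_true(all(mean_dsb("alpha", seq(1, 260, 1), CAL) <=
                    mean_lesions("alpha", seq(1, 260, 1), CAL) / 2 + 1e-12))
  for (p in c("electron", "proton", "alpha")) {
    expect_true(all(diff(mean_dsb(p, seq(0.5, 250, 0.5), CAL)) >= 0))
  }
})

test_that("threshold LETs solve to the printed onsets in the printed order", {
  cluster <- vapply(c("electron", "proton", "alpha"),
                    function(p) min_let_for(p, "total_lesions", 2, cal = CAL),
                    numeric(1))
  expect_equal(unname(cluster), c(7.1, 9.4, 11.5), tolerance = 1e-2)
  dsb <- vapply(c("electron", "proton", "alpha"),
                function(p) min_let_for(p, "dsb", 1, cal = CAL), numeric(1))
  expect_equal(unname(dsb), c(9.0, 11.8, 15.2), tolerance = 1e-2)
  expect_true(all(diff(cluster) > 0) && all(diff(dsb) > 0))
  expect_error(min_let_for("alpha", "total_lesions", 1e6, cal = CAL),
               "not attainable")
})

test_that("stochastic voxel damage matches its calibrated means", {
  n <- 1e5
  d <- sample_voxel_damage("alpha", 103.4, n = n, seed = 5, cal = CAL)
  expect_lt(abs(mean(d$total) - 23.1), 3 * sqrt(23.1 / n))
  expect_true(all(d$dsb <= floor(d$ssb / 2)))
  expect_true(all(d$total == d$ssb + d$base))
  expect_identical(d, sample_voxel_damage("alpha", 103.4, n = n, seed = 5, cal = CAL))
  # brute-force agreement across random configurations
  set.seed(99)
  cfg <- data.frame(particle = sample(c("electron", "proton", "alpha"), 8, TRUE),
                    let = runif(8, 2, 200))
  for (i in seq_len(8)) {
    lam <- mean_lesions(cfg$particle[i], cfg$let[i], CAL)
    s <- sample_voxel_damage(cfg$particle[i], cfg$let[i], n = 2e4,
                             seed = 100 + i, cal = CAL)
    expect_lt(abs(mean(s$total) - lam), 3 * sqrt(lam / 2e4) + 1e-12)
    expect_lt(abs(mean(s$ssb) - decompose_lesions(cfg$particle[i], cfg$let[i],
                                                  CAL)$ssb_mean),
              3 * sqrt(lam / 2e4) + 1e-12)
  }
})
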