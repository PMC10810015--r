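test_that("H2O2 curves hit the printed maxima and onset", {
  expect_equal(g_value("H2O2", "alpha", 262.2, CAL), 1.44)
  expect_equal(g_value("H2O2", "proton", 81.5, CAL), 1.15)
  expect_equal(g_value("H2O2", "proton", 5.0, CAL), 0)
  expect_equal(g_value("H2O2", "alpha", 2, CAL), 0)
  grid <- seq(0, 300, by = 0.5)
  for (p in c("electron", "proton", "alpha")) {
    expect_true(all(diff(g_value("H2O2", p, grid, CAL)) >= 0))
  }
  expect_lt(max(g_value("H2O2", "electron", grid, CAL)), 0.3)
})

test_that("radical curves peak at the printed LETs and stay non-negative", {
  expect_equal(peak_let("OH", "alpha", CAL), 66, tolerance = 0.1)
  expect_equal(peak_let("OH", "proton", CAL), 66, tolerance = 0.1)
  expect_equal(peak_let("e_aq", "proton", CAL), 30, tolerance = 0.1)
  expect_equal(peak_let("H", "alpha", CAL), 100, tolerance = 0.1)
  expect_error(peak_let("H2O2", "alpha", CAL), "no peak")
  grid <- seq(0, 300, by = 0.5)
  for (sp in c("OH", "e_aq", "H")) {
    for (p in c("proton", "alpha")) {
      g <- g_value(sp, p, grid, CAL)
      expect_true(all(g >= 0))
      # unimodal: rises to the peak then declines
      pk <- which.max(g)
      expect_true(all(diff(g[seq_len(pk)]) > 0))
      expect_true(all(diff(g[pk:length(g)]) < 0))
    }
  }
  expect_error(g_value("OH", "electron", 10, CAL), "proton and alpha")
})

test_that("OH rise rates equal the configured values and alpha exceeds proton", {
  expect_equal(oh_rise_rate("alpha", cal = CAL), 0.054, tolerance = 1e-6)
  expect_equal(oh_rise_rate("proton", cal = CAL), 0.047, tolerance = 1e-6)
  expect_gt(oh_rise_rate("alpha", cal = CAL), oh_rise_rate("proton", cal = CAL))
  # post-peak window slope is negative
  expect_lt(oh_rise_rate("alpha", window = c(70, 150), cal = CAL), 0)
})

test_that("curves are continuous at every segment joint", {
  eps <- 1e-7
  joints <- c(5, 30, 66, 100)
  for (sp in c("OH", "e_aq", "H", "H2O2")) {
    for (p in c("proton", "alpha")) {
      left <- g_value(sp, p, joints - eps, CAL)
      right <- g_value(sp, p, joints + eps, CAL)
      expect_true(all(abs(left - right) < 1e-5))
    }
  }
})

test_that("g_curve returns the tidy grid", {
  gc <- g_curve("OH", "alpha", seq(0, 100, 10), CAL)
  expect_s3_class(gc, "g_curve")
  expect_equal(nrow(gc), 11)
  expect_equal(gc$g, g_value("OH", "alpha", gc$let, CAL))
})
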