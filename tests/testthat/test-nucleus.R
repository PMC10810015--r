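test_that("track counts follow the fixed-energy fluence arithmetic", {
  expect_equal(n_tracks(0.2, CAL), 325)
  expect_equal(n_tracks(162.4, CAL), 0.400, tolerance = 1e-3)
  expect_equal(n_tracks(8.6, CAL), 7.558, tolerance = 1e-3)
  lets <- c(0.2, 1.7, 26.1, 162.4, 262.2)
  expect_equal(n_tracks(lets, CAL) * lets * 4, rep(260, 5), tolerance = 1e-9)
  expect_error(n_tracks(0, CAL), "positive")
})

test_that("benchmark report reproduces the published ion tallies", {
  rep <- cluster_report("per_track", CAL)
  ref <- reference_scenarios()
  # anchored cluster sizes are exact
  anchored <- !is.na(ref$cluster_size_ref) & ref$let %in% c(162.4, 103.4, 41.3, 26.1)
  expect_equal(rep$cluster_size[anchored], ref$cluster_size_ref[anchored],
               tolerance = 1e-6)
  # electron site counts are anchors of the electron lesion calibration
  el <- ref$particle == "electron"
  expect_equal(rep$damage_sites[el], ref$damage_sites_ref[el], tolerance = 1e-6)
  # published cluster sizes "<1" stay below one
  expect_true(all(rep$cluster_size[is.na(ref$cluster_size_ref)] < 1))
  # remaining printed cells for alpha and for high-LET protons within 10%
  check <- ref$particle == "alpha" | (ref$particle == "proton" & ref$let > 5)
  expect_true(all(abs(rep$damage_sites[check] - ref$damage_sites_ref[check]) /
                    ref$damage_sites_ref[check] < 0.10))
  ok_cluster <- check & !is.na(ref$cluster_size_ref)
  expect_true(all(abs(rep$cluster_size[ok_cluster] - ref$cluster_size_ref[ok_cluster]) /
                    ref$cluster_size_ref[ok_cluster] < 0.10))
})

test_that("site-counting modes are ordered and per-voxel cluster size tends to one", {
  lets <- c(0.5, 2, 8.6, 41.3, 103.4)
  for (p in c("electron", "proton", "alpha")) {
    expect_true(all(damage_sites(p, lets, "per_track", CAL) >=
                      damage_sites(p, lets, "per_voxel", CAL)))
  }
  expect_equal(cluster_size("proton", 0.7, "per_voxel", CAL),
               0.02704853 / (1 - exp(-0.02704853)), tolerance = 1e-6)
  # lambda -> 0 limit
  expect_equal(cluster_size("proton", 0.58, "per_voxel", CAL), 1, tolerance = 0.01)
})

test_that("cluster size rises with LET while damage sites fall", {
  for (p in c("proton", "alpha")) {
    hi <- if (p == "proton") 80 else 260
    sc <- cluster_scan(p, seq(2, hi, length.out = 100), "per_track", CAL)
    expect_true(all(diff(sc$cluster_size) > 0))
    expect_true(all(diff(sc$damage_sites) < 0))
  }
})

test_that("stochastic nucleus irradiation converges to the deterministic formulas", {
  reps <- 400
  sim <- simulate_nucleus("alpha", energy = 100, reps = reps, seed = 17,
                          mode = "per_track", cal = CAL)
  expect_identical(sim, simulate_nucleus("alpha", energy = 100, reps = reps,
                                         seed = 17, mode = "per_track", cal = CAL))
  expect_equal(unique(sim$energy_kev), 260, tolerance = 1e-9)
  det_sites <- damage_sites("alpha", sim$let[1], "per_track", CAL)
  se <- stats::sd(sim$damage_sites) / sqrt(reps)
  expect_lt(abs(mean(sim$damage_sites) - det_sites), 3 * se + 1e-9)
  expect_lt(abs(mean(sim$cluster_size) - cluster_size("alpha", sim$let[1],
                                                      "per_track", CAL)),
            3 * stats::sd(sim$cluster_size) / sqrt(reps))
  # at lambda ~ 10.8 essentially every candidate voxel is hit, so the
  # per-rep site count is almost surely constant (zero sample variance);
  # allow the residual exp(-lambda)-sized offset alongside the MC error
  simv <- simulate_nucleus("proton", let_track_avg = 41.3, reps = reps,
                           seed = 19, mode = "per_voxel", cal = CAL)
  detv <- damage_sites("proton", 41.3, "per_voxel", CAL)
  expect_lt(abs(mean(simv$damage_sites) - detv),
            3 * stats::sd(simv$damage_sites) / sqrt(reps) + 1e-3)
})
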