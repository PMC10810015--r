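# Nucleus-scale scoring: tracks through a 4 um spherical nucleus receiving a
# fixed 260 keV (nominally 2 Gy), damage sites (voxels with at least one
# lesion) and cluster size (lesions per voxel).
#
# Track chords are the full diameter: 260 keV / (0.2 keV/um * 4 um) = 325
# tracks reproduces the published "about 320" for 500 keV electrons, which a
# mean-chord (2d/3) convention would not. Each track exposes N_v = 4
# candidate voxels, a value recovered from self-consistency of the published
# site counts (for medium/high-LET rows, sites = 4 * n_tracks within ~1%);
# it is a reconstruction, tagged "derived" in the calibration set.
#
# Two site-counting modes:
#   per_track: all N_v candidate voxels of any track that produced a lesion
#     count as sites (per-track probability 1 - exp(-N_v * lambda)); this is
#     the convention that reproduces the published tallies and is the
#     default.
#   per_voxel: only individually damaged voxels count (per-voxel probability
#     1 - exp(-lambda)).

SITE_MODES <- c("per_track", "per_voxel")

#' Nucleus model constants
#'
#' @param cal A calibration set.
#' @return A list with `diameter_um`, `energy_kev`, `dose_gy`,
#'   `n_voxels_per_track`.
#' @export
nucleus_model <- function(cal = calibration_set()) {
  list(
    diameter_um = cal_value(cal, "nucleus_diameter_um"),
    energy_kev = cal_value(cal, "nucleus_energy_kev"),
    dose_gy = cal_value(cal, "nucleus_dose_gy"),
    n_voxels_per_track = cal_value(cal, "n_voxels_per_track")
  )
}

#' Expected number of tracks delivering the nucleus energy
#'
#' `E_total / (LET * d)`: each track deposits `LET * d` keV along a full-
#' diameter chord, and enough (generally fractional) tracks arrive to deposit
#' exactly 260 keV.
#'
#' @param let_track_avg Track-averaged LET in keV/um; vectorised, positive.
#' @param cal A calibration set.
#' @return Expected track count (fractional).
#' @export
#' @examples
#' n_tracks(0.2) # 325 tracks of 500 keV electrons for 2 Gy
n_tracks <- function(let_track_avg, cal = calibration_set()) {
  if (any(let_track_avg <= 0)) abort("LET must be positive")
  cal_value(cal, "nucleus_energy_kev") /
    (let_track_avg * cal_value(cal, "nucleus_diameter_um"))
}

#' Expected damage sites per nucleus
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param let_track_avg Track-averaged LET in keV/um; vectorised.
#' @param mode Site-counting mode, `"per_track"` (default) or `"per_voxel"`.
#' @param cal A calibration set.
#' @return Expected number of voxels scored as damage sites.
#' @export
#' @examples
#' damage_sites("alpha", 8.6) # ~30
damage_sites <- function(particle, let_track_avg, mode = c("per_track", "per_voxel"),
                         cal = calibration_set()) {
  mode <- arg_match(mode)
  lam <- mean_lesions(particle, let_track_avg, cal)
  nv <- cal_value(cal, "n_voxels_per_track")
  rate <- if (mode == "per_track") nv * lam else lam
  n_tracks(let_track_avg, cal) * nv * (1 - exp(-rate))
}

#' Expected cluster size
#'
#' In `per_track` mode the cluster size is the mean lesion count per candidate
#' voxel, `lambda(L)`; in `per_voxel` mode it is the mean per damaged voxel,
#' `lambda / (1 - exp(-lambda))`, which tends to 1 as `lambda` tends to 0.
#'
#' @inheritParams damage_sites
#' @return Expected lesions per (candidate or damaged) voxel.
#' @export
#' @examples
#' cluster_size("alpha", 162.4) # 39.8
cluster_size <- function(particle, let_track_avg, mode = c("per_track", "per_voxel"),
                         cal = calibration_set()) {
  mode <- arg_match(mode)
  lam <- mean_lesions(particle, let_track_avg, cal)
  if (mode == "per_track") return(lam)
  ifelse(lam < 1e-12, 1, lam / (1 - exp(-lam)))
}

#' Published benchmark scenarios
#'
#' The ten particle/energy scenarios with published cluster-size and
#' damage-site tallies, used as calibration anchors and validation checks.
#' `let` is the scenario's printed track-averaged LET (including the proton
#' 1 MeV row's printed 26.1 keV/um, which matches neither registry column
#' and is therefore carried as an explicit override). `range_um` is the
#' published particle range, echoed rather than modelled. Reference cluster
#' sizes printed as "<1" are stored as `NA` with the convention that the
#' computed value must fall below one.
#'
#' @return A tibble with columns `particle`, `energy_mev`, `let`, `range_um`,
#'   `cluster_size_ref`, `damage_sites_ref`.
#' @export
reference_scenarios <- function() {
  tibble(
    particle = c(rep("alpha", 4), rep("proton", 4), rep("electron", 2)),
    energy_mev = c(2, 4, 50, 100, 0.5, 1, 50, 100, 0.1, 0.5),
    let = c(162.4, 103.4, 15.2, 8.6, 41.3, 26.1, 1.2, 0.7, 0.4, 0.2),
    range_um = c(11.2, 27.1, 1.8, 6.4, 8.9, 24.6, 22.3, 77.2, 0.14, 1.8),
    cluster_size_ref = c(39.8, 23.1, 2.8, 1.4, 10.8, 6.3, NA, NA, NA, NA),
    damage_sites_ref = c(1.6, 2.5, 17.3, 30.3, 6.3, 10.1, 47.4, 47.1, 67.9, 86.7)
  )
}

#' Cluster-size / damage-site report over the benchmark scenarios
#'
#' Evaluates the deterministic nucleus formulas at every
#' [reference_scenarios()] row.
#'
#' @param mode Site-counting mode.
#' @param cal A calibration set.
#' @return A tibble of class `cluster_report` with columns `particle`,
#'   `energy_mev`, `let`, `range_um`, `n_tracks`, `cluster_size`,
#'   `damage_sites`, `mode`.
#' @export
#' @examples
#' cluster_report()
cluster_report <- function(mode = c("per_track", "per_voxel"),
                           cal = calibration_set()) {
  mode <- arg_match(mode)
  sc <- reference_scenarios()
  out <- mutate(
    select(sc, "particle", "energy_mev", "let", "range_um"),
    n_tracks = n_tracks(.data$let, cal),
    cluster_size = map2_dbl(.data$particle, .data$let,
                            ~ cluster_size(.x, .y, mode, cal)),
    damage_sites = map2_dbl(.data$particle, .data$let,
                            ~ damage_sites(.x, .y, mode, cal)),
    mode = mode
  )
  class(out) <- c("cluster_report", class(out))
  out
}

#' Cluster-size / damage-site scan over an LET grid
#'
#' @param particle Particles to scan.
#' @param let_track_avg LET grid in keV/um.
#' @param mode Site-counting mode.
#' @param cal A calibration set.
#' @return A tibble of class `cluster_scan` with columns `particle`, `let`,
#'   `n_tracks`, `cluster_size`, `damage_sites`, `mode`.
#' @export
cluster_scan <- function(particle = c("proton", "alpha"),
                         let_track_avg = seq(1, 160, by = 1),
                         mode = c("per_track", "per_voxel"),
                         cal = calibration_set()) {
  mode <- arg_match(mode)
  out <- purrr::map(particle, function(p) {
    tibble(particle = p, let = let_track_avg,
           n_tracks = n_tracks(let_track_avg, cal),
           cluster_size = cluster_size(p, let_track_avg, mode, cal),
           damage_sites = damage_sites(p, let_track_avg, mode, cal),
           mode = mode)
  }) |> purrr::list_rbind()
  class(out) <- c("cluster_scan", class(out))
  out
}

#' Stochastic nucleus irradiation
#'
#' Simulates `reps` independent deliveries of the fixed nucleus energy. The
#' expected (fractional) track count is rounded up to whole tracks; the last
#' track's contributions are weighted by the fractional remainder so each
#' repetition deposits exactly the nominal 260 keV. Every track exposes
#' `N_v` candidate voxels whose lesion tallies come from
#' [sample_voxel_damage()]; sites and cluster size are scored per `mode`.
#' Means over repetitions converge to [damage_sites()] and [cluster_size()].
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param energy Particle energy in the registry unit (MeV for ions, keV for
#'   electrons); translated to track-averaged LET via [lookup_let()]. Ignored
#'   when `let_track_avg` is given directly.
#' @param let_track_avg Optional explicit LET override in keV/um.
#' @param reps Number of independent repetitions.
#' @param seed Optional integer seed.
#' @param mode Site-counting mode.
#' @param cal A calibration set.
#' @return A tibble with one row per repetition: `rep`, `particle`, `let`,
#'   `n_tracks`, `lesions_total`, `damage_sites`, `cluster_size`,
#'   `energy_kev`, `mode`.
#' @export
simulate_nucleus <- function(particle, energy = NULL, let_track_avg = NULL,
                             reps = 1, seed = NULL,
                             mode = c("per_track", "per_voxel"),
                             cal = calibration_set()) {
  mode <- arg_match(mode)
  .check_particle(particle)
  stopifnot(reps >= 1)
  if (is.null(let_track_avg)) {
    if (is.null(energy)) abort("give either energy or let_track_avg")
    let_track_avg <- lookup_let(particle, energy)$let_track_avg
  }
  nt <- n_tracks(let_track_avg, cal)
  nv <- cal_value(cal, "n_voxels_per_track")
  k <- ceiling(nt)
  frac <- nt - (k - 1) # weight of the last, partial track

  .with_seed(seed, {
    purrr::map(seq_len(reps), function(r) {
      draws <- sample_voxel_damage(particle, let_track_avg, n = k * nv, cal = cal)
      counts <- matrix(draws$total, nrow = k) # tracks x candidate voxels
      w <- c(rep(1, k - 1), frac)
      lesions_total <- sum(counts * w)
      sites <- if (mode == "per_track") {
        sum(w * nv * (rowSums(counts) > 0))
      } else {
        sum(w * rowSums(counts > 0))
      }
      csize <- if (mode == "per_track") {
        lesions_total / (nt * nv)
      } else if (sites > 0) lesions_total / sites else 0
      tibble(rep = r, particle = particle, let = let_track_avg, n_tracks = nt,
             lesions_total = lesions_total, damage_sites = sites,
             cluster_size = csize,
             energy_kev = nt * let_track_avg *
               cal_value(cal, "nucleus_diameter_um"),
             mode = mode)
    }) |> purrr::list_rbind()
  })
}
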