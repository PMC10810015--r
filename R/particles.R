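# Registry of the three particle types with their published energy <-> LET
# rows, and log-log interpolation between rows.

.particle_rows <- function() {
  tribble_rows <- rbind(
    # alpha: energy in MeV
    cbind(p = 1, rbind(
      c(0.75, 233.8, 262.2), c(1, 219, 221.7), c(2, 161.4, 162.4),
      c(4, 101.3, 103.4), c(7, 67.4, 69.5), c(10, 51.5, 53.4),
      c(20, 30.6, 31.4), c(50, 14.6, 15.2), c(100, 8.1, 8.6), c(200, 4.5, 4.9)
    )),
    # proton: energy in MeV
    cbind(p = 2, rbind(
      c(0.1, 70.6, 81.5), c(0.2, 66.0, 66.2), c(0.5, 41.0, 41.3),
      c(1, 26.7, 28.0), c(2, 15.9, 16.9), c(5, 7.9, 8.8),
      c(10, 4.8, 5.0), c(20, 2.6, 2.8), c(50, 1.2, 1.3), c(100, 0.7, 0.7)
    )),
    # electron: energy in keV
    cbind(p = 3, rbind(
      c(0.1, 28.7, 28.7), c(0.2, 26.6, 28.5), c(0.5, 17, 18.6),
      c(1, 11.2, 12.5), c(2, 7.1, 7.3), c(5, 3.6, 3.8),
      c(10, 2.1, 2.2), c(50, 0.7, 0.7), c(100, 0.4, 0.4), c(500, 0.2, 0.2)
    ))
  )
  tibble(
    particle = c("alpha", "proton", "electron")[tribble_rows[, 1]],
    energy = tribble_rows[, 2],
    energy_unit = ifelse(tribble_rows[, 1] == 3, "keV", "MeV"),
    let_initial = tribble_rows[, 3],
    let_track_avg = tribble_rows[, 4]
  )
}

#' Particle energy/LET registry
#'
#' The ten tabulated (energy, initial LET, track-averaged LET) rows per
#' particle used throughout the package. Proton and alpha energies are in MeV;
#' electron energies are in keV (the `energy_unit` column makes this
#' explicit). LET is in keV/um for all particles.
#'
#' @param particle Optionally restrict to `"electron"`, `"proton"` or
#'   `"alpha"`.
#' @return A tibble with columns `particle`, `energy`, `energy_unit`,
#'   `let_initial`, `let_track_avg`.
#' @export
#' @examples
#' particle_table("alpha")
particle_table <- function(particle = NULL) {
  rows <- .particle_rows()
  if (is.null(particle)) return(rows)
  .check_particle(particle)
  filter(rows, .data$particle == !!particle)
}

# log-log linear interpolation of y(x) through tabulated (xs, ys)
.loglog_interp <- function(x, xs, ys) {
  exp(stats::approx(log(xs), log(ys), xout = log(x), rule = 1)$y)
}

#' Look up LET at a given particle energy
#'
#' Returns the tabulated row exactly when `energy` matches one; otherwise
#' interpolates linearly in log(energy)-log(LET) space between the bracketing
#' rows (LET-energy relations are close to power laws over these decades, and
#' log-space interpolation can never produce negative values).
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param energy Energy in the particle's tabulated unit (MeV for proton and
#'   alpha, keV for electron); vectorised. Must lie within the tabulated range.
#' @return A tibble with columns `particle`, `energy`, `let_initial`,
#'   `let_track_avg` (keV/um).
#' @export
#' @examples
#' lookup_let("alpha", 2)      # a tabulated row
#' lookup_let("electron", 0.3) # interpolated between the 0.2 and 0.5 keV rows
lookup_let <- function(particle, energy) {
  .check_particle(particle)
  rows <- particle_table(particle)
  rng <- range(rows$energy)
  if (any(energy < rng[1] | energy > rng[2])) {
    abort(sprintf("energy outside tabulated range [%g, %g] %s for %s",
                  rng[1], rng[2], rows$energy_unit[1], particle))
  }
  tibble(
    particle = particle,
    energy = energy,
    let_initial = .loglog_interp(energy, rows$energy, rows$let_initial),
    let_track_avg = .loglog_interp(energy, rows$energy, rows$let_track_avg)
  )
}

#' Invert the energy/LET table
#'
#' Inverse of [lookup_let()] on the track-averaged LET column, using the same
#' log-log interpolation, so the round trip through a tabulated row is exact.
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param let_track_avg Track-averaged LET in keV/um; vectorised. Must lie
#'   within the particle's tabulated LET range.
#' @return Energy in the particle's tabulated unit (numeric vector).
#' @export
#' @examples
#' let_to_energy("alpha", 162.4) # 2 MeV
let_to_energy <- function(particle, let_track_avg) {
  .check_particle(particle)
  rows <- particle_table(particle)
  rng <- range(rows$let_track_avg)
  # tolerate one ulp of log/exp round-off at the interval ends
  if (any(let_track_avg < rng[1] * (1 - 1e-12) | let_track_avg > rng[2] * (1 + 1e-12))) {
    abort(sprintf("LET outside tabulated range [%g, %g] keV/um for %s",
                  rng[1], rng[2], particle))
  }
  let_track_avg <- pmin(pmax(let_track_avg, rng[1]), rng[2])
  # LET decreases with energy: reverse so approx sees increasing x
  .loglog_interp(let_track_avg, rev(rows$let_track_avg), rev(rows$energy))
}
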