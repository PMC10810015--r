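# LET-dependent radiation-chemical yields (G-values, species per 100 eV) for
# OH, e_aq, H and H2O2, at the fixed 100 ns snapshot. G-values are nearly
# constant after ~10 ns, which is what justifies a single-snapshot module; no
# diffusion-reaction kinetics are modelled.
#
# Radical curves are piecewise linear: a rise from a baseline G0 to the
# species' peak LET, then a slow linear decline. H2O2, a recombination
# product, is monotone: zero below a 5 keV/um onset, linear to a 100 keV/um
# breakpoint, then a shallower segment pinned to the printed maximum at the
# ion's maximum tabulated LET. Only the rise rates (OH), peak LETs, H2O2
# maxima, onset and the electron ceiling are data-pinned; baselines and
# decline rates are flagged assumptions in the calibration set.

.radical_rise <- function(cal, species, particle) {
  switch(species,
    OH = cal_value(cal, "oh_rise_rate", particle),
    e_aq = cal_value(cal, "radical_rise_rate_eaq", particle),
    H = cal_value(cal, "radical_rise_rate_h", particle)
  )
}

.g_h2o2 <- function(cal, particle, let) {
  onset <- cal_value(cal, "h2o2_onset_let")
  brk <- cal_value(cal, "h2o2_breakpoint_let")
  s1 <- switch(particle,
    proton = cal_value(cal, "h2o2_slope_proton"),
    alpha = cal_value(cal, "h2o2_rise_alpha"),
    electron = cal_value(cal, "h2o2_rise_electron")
  )
  s2 <- switch(particle,
    proton = s1 * cal_value(cal, "h2o2_post_break_factor"),
    alpha = cal_value(cal, "h2o2_slope2_alpha"),
    electron = s1 # electron curve keeps one shallow segment
  )
  s1 * pmax(0, pmin(let, brk) - onset) + s2 * pmax(0, let - brk)
}

#' G-value of a radiolysis species at 100 ns
#'
#' @param species `"OH"`, `"e_aq"`, `"H"` or `"H2O2"`.
#' @param particle `"proton"` or `"alpha"` for every species; `"electron"` is
#'   supported for the H2O2 ceiling curve only.
#' @param let_track_avg Track-averaged LET in keV/um, in \[0, 300\];
#'   vectorised.
#' @param cal A calibration set.
#' @return Yield in molecules per 100 eV (numeric vector).
#' @export
#' @examples
#' g_value("H2O2", "alpha", 262.2) # 1.44
#' g_value("OH", "proton", 30)
g_value <- function(species, particle, let_track_avg, cal = calibration_set()) {
  species <- arg_match(species, SPECIES)
  .check_particle(particle)
  .check_let(let_track_avg)
  if (species == "H2O2") return(.g_h2o2(cal, particle, let_track_avg))
  if (particle == "electron") {
    abort("radical G-value curves are parameterised for proton and alpha only")
  }
  g0 <- cal_value(cal, "radical_g0", species)
  peak <- cal_value(cal, "radical_peak_let", species)
  rise <- .radical_rise(cal, species, particle)
  decline <- cal_value(cal, "radical_decline_rate", species)
  g0 + rise * pmin(let_track_avg, peak) - decline * pmax(0, let_track_avg - peak)
}

#' G-value curve over an LET grid
#'
#' Tidy evaluation of [g_value()] over every requested species/particle/LET
#' combination.
#'
#' @param species Character vector of species.
#' @param particle Character vector of particles.
#' @param let_track_avg LET grid in keV/um.
#' @param cal A calibration set.
#' @return A tibble of class `g_curve` with columns `species`, `particle`,
#'   `let`, `g`.
#' @export
g_curve <- function(species = c("OH", "e_aq", "H", "H2O2"),
                    particle = c("proton", "alpha"),
                    let_track_avg = seq(0, 300, by = 1),
                    cal = calibration_set()) {
  grid <- tidyr::expand_grid(species = species, particle = particle)
  out <- purrr::pmap(grid, function(species, particle) {
    g <- g_value(species, particle, let_track_avg, cal)
    tibble(species = species, particle = particle, let = let_track_avg, g = g)
  }) |> purrr::list_rbind()
  class(out) <- c("g_curve", class(out))
  out
}

#' LET of maximal radical yield
#'
#' Grid-search argmax of [g_value()] over \[0, 300\] keV/um at 0.1 keV/um
#' resolution. H2O2 has no interior maximum (it is monotone) and is rejected.
#'
#' @param species `"OH"`, `"e_aq"` or `"H"`.
#' @param particle `"proton"` or `"alpha"`.
#' @param cal A calibration set.
#' @return Peak LET in keV/um.
#' @export
#' @examples
#' peak_let("OH", "alpha") # 66
peak_let <- function(species, particle, cal = calibration_set()) {
  species <- arg_match(species, SPECIES)
  if (species == "H2O2") abort("H2O2 is monotone in LET and has no peak")
  grid <- seq(0, 300, by = 0.1)
  grid[which.max(g_value(species, particle, grid, cal))]
}

#' Low-LET rise rate of the OH curve
#'
#' Ordinary least-squares slope of `g_value("OH", particle, L)` on a
#' 1 keV/um grid over `window`. The default window lies entirely inside the
#' rising segment, so the slope equals the configured rise rate.
#'
#' @param particle `"proton"` or `"alpha"`.
#' @param window LET window in keV/um.
#' @param cal A calibration set.
#' @return Slope in molecules per 100 eV per keV/um.
#' @export
#' @examples
#' oh_rise_rate("alpha") # 0.054
oh_rise_rate <- function(particle, window = c(5, 60), cal = calibration_set()) {
  .check_particle(particle)
  if (particle == "electron") abort("OH rise rate is defined for proton and alpha only")
  lets <- seq(window[1], window[2], by = 1)
  unname(coef(lm(g_value("OH", particle, lets, cal) ~ lets))[2])
}
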