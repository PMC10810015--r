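# Calibration storage: every numeric constant of the surrogate models, each
# tagged with its provenance:
#   printed    -- value printed in the source measurements/tables
#   anchored   -- coefficient fitted exactly through printed anchor points
#   derived    -- arithmetic consequence of printed values
#   assumption -- shape-only choice, not numerically constrained by data

PROVENANCE_TAGS <- c("printed", "anchored", "derived", "assumption")

.entry <- function(value, provenance, citation) {
  stopifnot(provenance %in% PROVENANCE_TAGS)
  list(value = value, provenance = provenance, citation = citation)
}

# Base (non-derived) entries: printed constants and shape assumptions.
.cal_base <- function() {
  e <- .entry
  list(
    # ionization surrogate
    ion_slope = e(c(alpha = 0.10, proton = 0.11, electron = 0.14),
                  "printed", "linear rate of ionizations per keV/um"),
    ion_anchor_let = e(c(alpha = 162.4, proton = 81.5, electron = 28.7),
                       "printed", "track-averaged LET of each particle's max-LET anchor"),
    ion_anchor_count = e(c(alpha = 17.0, proton = 9.4, electron = 4.4),
                         "printed", "ionizations per voxel traversal at the anchor LET"),
    # voxel geometry
    voxel_volume_nm3 = e(36.0, "printed", "hydrated-DNA voxel volume"),
    voxel_base_pairs = e(15, "printed", "base pairs per voxel"),
    voxel_water_count = e(600, "printed", "water molecules per voxel (20 per nucleotide)"),
    water_molecule_volume_nm3 = e(0.0299, "printed", "volume of one water molecule"),
    voxel_composition = e(c(THF = 30, TMP = 30, PU = 15, PY = 15),
                          "printed", "model molecules per voxel"),
    dna_density_g_cm3 = e(1.4, "printed", "DNA mass density"),
    direct_fraction = e(0.5, "printed",
                        "fraction of deposited energy assigned to the DNA itself"),
    # measured lesion yields and LEE cross-sections
    sigma_strand_break_nm2 = e(3.8e-2, "printed", "LEE strand-break cross-section"),
    sigma_base_lesion_nm2 = e(4.8e-2, "printed", "LEE base-lesion cross-section"),
    yield_ssb_direct_per_ev = e(2.1e-2, "printed", "SSB yield of DNA cation radicals"),
    yield_ssb_indirect_per_ev = e(1.2e-2, "printed", "SSB yield of water radicals"),
    yield_base_indirect_per_ev = e(1.36e-2, "printed", "base-lesion yield of water radicals"),
    # lesion-model anchors
    lambda_anchor_let_alpha = e(c(162.4, 103.4, 11.5), "printed",
                                "alpha LETs anchoring the total-lesion quadratic"),
    lambda_anchor_val_alpha = e(c(39.8, 23.1, 2.0), "printed",
                                "alpha mean total lesions at the anchor LETs"),
    lambda_anchor_let_proton = e(c(41.3, 26.1, 9.4), "printed",
                                 "proton LETs anchoring the total-lesion quadratic"),
    lambda_anchor_val_proton = e(c(10.8, 6.3, 2.0), "printed",
                                 "proton mean total lesions at the anchor LETs"),
    electron_site_anchor_let = e(c(0.2, 0.4), "printed",
                                 "electron LETs with published nucleus damage-site counts"),
    electron_site_anchor_sites = e(c(86.7, 67.9), "printed",
                                   "published electron damage-site counts at 2 Gy"),
    electron_cluster_anchor = e(c(7.1, 2.0), "printed",
                                "electron clustered-damage onset (LET, lesions)"),
    dsb_min_let = e(c(electron = 9.0, proton = 11.8, alpha = 15.2),
                    "printed", "minimum track-averaged LET for one DSB per voxel"),
    cluster_min_let = e(c(electron = 7.1, proton = 9.4, alpha = 11.5),
                        "printed", "minimum LET for a clustered lesion (>= 2) per voxel"),
    # radiolysis curve constraints
    oh_rise_rate = e(c(proton = 0.047, alpha = 0.054),
                     "printed", "low-LET rise rate of the OH G-value"),
    radical_peak_let = e(c(OH = 66, e_aq = 30, H = 100),
                         "printed", "LET of maximal radical yield"),
    h2o2_onset_let = e(5, "printed",
                       "LET below which intra-track H2O2 formation is negligible"),
    h2o2_breakpoint_let = e(100, "printed",
                            "LET where the H2O2 rise changes to a lower rate"),
    h2o2_max_let = e(c(proton = 81.5, alpha = 262.2), "printed",
                     "maximum track-averaged LET of each ion"),
    h2o2_max_g = e(c(proton = 1.15, alpha = 1.44), "printed",
                   "H2O2 G-value at each ion's maximum LET"),
    h2o2_electron_ceiling = e(0.3, "printed", "upper bound on electron H2O2 G-values"),
    # nucleus scale
    nucleus_diameter_um = e(4.0, "printed", "nucleus diameter"),
    nucleus_energy_kev = e(260, "printed", "deposited energy per nucleus"),
    nucleus_dose_gy = e(2.0, "printed", "nominal absorbed dose for 260 keV"),
    # shape-only assumptions (no numeric data constrain them)
    radical_g0 = e(c(OH = 0.5, e_aq = 0.5, H = 0.5), "assumption",
                   "zero-LET baseline G-value of each radical; curve figures not numerically readable"),
    radical_rise_rate_eaq = e(c(proton = 0.045, alpha = 0.050), "assumption",
                              "e_aq low-LET rise rate; only the peak LET is constrained"),
    radical_rise_rate_h = e(c(proton = 0.010, alpha = 0.012), "assumption",
                            "H low-LET rise rate; only the peak LET is constrained"),
    radical_decline_rate = e(c(OH = 0.008, e_aq = 0.004, H = 0.002), "assumption",
                             "post-peak decline rate per keV/um ('decrease slowly')"),
    h2o2_rise_alpha = e(0.010, "assumption",
                        "alpha H2O2 first-segment slope; below the proton slope at equal LET"),
    h2o2_post_break_factor = e(0.3, "assumption",
                               "proton H2O2 slope ratio beyond the breakpoint"),
    h2o2_rise_electron = e(0.00095, "assumption",
                           "electron H2O2 slope; keeps the curve under the 0.3 ceiling"),
    lee_spectrum = e(
      c(bump_mean = 4, bump_sd = 1.5, bump_weight = 0.25,
        peak_mean = 9.5, peak_sd = 1.2, peak_weight = 0.60,
        tail_start = 15, tail_scale = 2.5, tail_weight = 0.15,
        e_min = 1, e_max = 25),
      "assumption",
      "shape-only mixture reproducing the 2-6 eV bump, 8-11 eV peak and >15 eV tail"
    ),
    n_voxels_per_track = e(4, "derived",
                           "candidate damaged voxels per track; self-consistency of the published site counts")
  )
}

# Derived and anchored entries, recomputed from the base entries.
.cal_derive <- function(base) {
  e <- .entry
  v <- function(name) base[[name]]$value

  ell <- v("voxel_volume_nm3")^(1 / 3)
  f_dir <- v("direct_fraction")
  sigma_sb <- v("sigma_strand_break_nm2")
  sigma_base <- v("sigma_base_lesion_nm2")
  n_areal <- 4 * v("voxel_base_pairs") / ell^2 # 60 nucleotides per voxel face area
  p_lee <- (sigma_sb + sigma_base) * n_areal
  sb_share <- sigma_sb / (sigma_sb + sigma_base)
  c_lin <- ell * (f_dir * v("yield_ssb_direct_per_ev") +
                    (1 - f_dir) * (v("yield_ssb_indirect_per_ev") +
                                     v("yield_base_indirect_per_ev")))

  ion_intercept <- v("ion_anchor_count") - v("ion_slope") * v("ion_anchor_let")

  # Electron low-LET lesion anchors: invert the per-track site-counting formula
  # against the published electron damage-site counts.
  n_v <- v("n_voxels_per_track")
  let_e <- v("electron_site_anchor_let")
  sites_e <- v("electron_site_anchor_sites")
  tracks_e <- v("nucleus_energy_kev") / (let_e * v("nucleus_diameter_um"))
  lam_e <- -log(1 - sites_e / (tracks_e * n_v)) / n_v

  anchors <- list(
    alpha = cbind(v("lambda_anchor_let_alpha"), v("lambda_anchor_val_alpha")),
    proton = cbind(v("lambda_anchor_let_proton"), v("lambda_anchor_val_proton")),
    electron = cbind(c(let_e, v("electron_cluster_anchor")[1]),
                     c(lam_e, v("electron_cluster_anchor")[2]))
  )
  coefs <- lapply(anchors, function(an) .solve_quadratic(an[, 1], an[, 2]))

  # DSB scale: one DSB at the printed minimum LET for each particle.
  consts <- list(ell = ell, f_dir = f_dir,
                 y_ssb_dir = v("yield_ssb_direct_per_ev"),
                 y_ssb_ind = v("yield_ssb_indirect_per_ev"),
                 y_base_ind = v("yield_base_indirect_per_ev"),
                 sb_share = sb_share)
  kd <- vapply(PARTICLES, function(p) {
    lmin <- v("dsb_min_let")[[p]]
    4 / .ssb_mean_eval(coefs[[p]], consts, lmin)^2
  }, numeric(1))

  # H2O2 segment slopes pinned to the printed maxima.
  onset <- v("h2o2_onset_let")
  brk <- v("h2o2_breakpoint_let")
  s1_proton <- v("h2o2_max_g")[["proton"]] / (v("h2o2_max_let")[["proton"]] - onset)
  s1_alpha <- v("h2o2_rise_alpha")
  s2_alpha <- (v("h2o2_max_g")[["alpha"]] - s1_alpha * (brk - onset)) /
    (v("h2o2_max_let")[["alpha"]] - brk)

  list(
    voxel_side_nm = e(ell, "derived", "cube root of the voxel volume"),
    nucleotide_areal_density_per_nm2 = e(n_areal, "derived",
                                         "60 nucleotides over the voxel face area"),
    p_lee_lesion = e(p_lee, "derived", "per-LEE lesion probability, (sigma_sb+sigma_base)*n_areal"),
    lee_sb_share = e(sb_share, "derived", "strand-break share of LEE lesions"),
    linear_lesion_rate = e(c_lin, "derived",
                           "non-LEE lesion mean per keV/um of track-averaged LET"),
    ion_intercept = e(ion_intercept, "anchored",
                      "intercept reconciling printed slopes with printed point anchors"),
    lambda_anchor_let_electron = e(anchors$electron[, 1], "derived",
                                   "electron lesion-anchor LETs (site inversion + clustered onset)"),
    lambda_anchor_val_electron = e(anchors$electron[, 2], "derived",
                                   "electron lesion-anchor means from published site counts"),
    lambda_coef_alpha = e(coefs$alpha, "anchored", "alpha total-lesion quadratic (a, b, c)"),
    lambda_coef_proton = e(coefs$proton, "anchored", "proton total-lesion quadratic (a, b, c)"),
    lambda_coef_electron = e(coefs$electron, "anchored", "electron total-lesion quadratic (a, b, c)"),
    dsb_scale = e(kd, "anchored", "DSB pairing scale; one DSB at the printed minimum LET"),
    h2o2_slope_proton = e(s1_proton, "anchored",
                          "proton H2O2 slope through the printed maximum"),
    h2o2_slope2_alpha = e(s2_alpha, "anchored",
                          "alpha post-breakpoint H2O2 slope through the printed maximum")
  )
}

#' Default calibration set
#'
#' Builds the full set of model constants used by every surrogate in the
#' package. Each constant carries a provenance tag (`printed`, `anchored`,
#' `derived` or `assumption`) and a one-line citation. Anchored and derived
#' entries are recomputed from the printed entries at construction time, so a
#' calibration set is always internally consistent; [check_calibration()]
#' verifies this for a deserialised object.
#'
#' @return An object of class `damage_calibration`: a named list of entries,
#'   each holding `value`, `provenance` and `citation`.
#' @seealso [load_calibration()], [save_calibration()], [tidy.damage_calibration()]
#' @export
#' @examples
#' cal <- calibration_set()
#' cal_value(cal, "voxel_side_nm")
#' dplyr::count(tidy(cal), provenance)
calibration_set <- function() {
  base <- .cal_base()
  out <- c(base, .cal_derive(base))
  structure(out, class = "damage_calibration")
}

#' Fetch one calibration value
#'
#' @param cal A `damage_calibration` object.
#' @param name Entry name, e.g. `"lambda_coef_alpha"`.
#' @param element Optional element name within a vector-valued entry.
#' @return The stored numeric value (scalar or named vector).
#' @export
cal_value <- function(cal, name, element = NULL) {
  stopifnot(inherits(cal, "damage_calibration"))
  if (is.null(cal[[name]])) abort(paste0("unknown calibration entry '", name, "'"))
  val <- cal[[name]]$value
  if (is.null(element)) val else val[[element]]
}

#' @export
print.damage_calibration <- function(x, ...) {
  tab <- table(vapply(x, function(e) e$provenance, character(1)))
  cat("<damage_calibration> ", length(x), " constants (",
      paste(names(tab), unname(tab), sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Tidy a calibration set into a provenance table
#'
#' One row per scalar component of every constant, with its provenance tag and
#' citation string.
#'
#' @param x A `damage_calibration` object.
#' @param ... Unused.
#' @return A tibble with columns `constant`, `component`, `value`,
#'   `provenance`, `citation`.
#' @export
tidy.damage_calibration <- function(x, ...) {
  purrr::imap(unclass(x), function(e, nm) {
    comp <- names(e$value)
    tibble(
      constant = nm,
      component = if (is.null(comp)) NA_character_ else comp,
      value = as.numeric(e$value),
      provenance = e$provenance,
      citation = e$citation
    )
  }) |> purrr::list_rbind()
}

#' @rdname tidy.damage_calibration
#' @return For `glance()`: a one-row tibble with counts of constants by
#'   provenance class.
#' @export
glance.damage_calibration <- function(x, ...) {
  tags <- vapply(x, function(e) e$provenance, character(1))
  tibble(
    n_constants = length(x),
    n_printed = sum(tags == "printed"),
    n_anchored = sum(tags == "anchored"),
    n_derived = sum(tags == "derived"),
    n_assumption = sum(tags == "assumption")
  )
}

#' Save / load a calibration set
#'
#' Serialisation uses JSON with full double precision, so a save/load round
#' trip reproduces every value bit-exactly. `load_calibration()` starts from
#' the package defaults, applies any overrides found in the file, and then
#' recomputes all anchored and derived constants, so overriding an anchor
#' propagates consistently. Printed constants may only be overridden with
#' `allow_override = TRUE`; anchored and derived constants can never be set
#' directly.
#'
#' @param cal A `damage_calibration` object.
#' @param path File path.
#' @param allow_override Permit overriding `printed` constants.
#' @return `save_calibration()` returns `path` invisibly; `load_calibration()`
#'   returns a `damage_calibration`.
#' @export
save_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "damage_calibration"))
  jsonlite::write_json(unclass(cal), path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path, allow_override = FALSE) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  raw <- jsonlite::read_json(path)
  base <- .cal_base()
  fixed <- names(.cal_derive(base))
  for (nm in names(raw)) {
    entry <- raw[[nm]]
    val <- entry$value
    if (is.list(val)) val <- unlist(val)
    if (nm %in% fixed) {
      # derived/anchored values are recomputed, never set; accept them silently
      # only when they match a fresh recomputation (round-trip case)
      next
    }
    if (is.null(base[[nm]])) abort(paste0("unknown calibration entry '", nm, "' in ", path))
    if (!isTRUE(all.equal(unname(as.numeric(base[[nm]]$value)), unname(as.numeric(val)),
                          tolerance = 0))) {
      if (base[[nm]]$provenance == "printed" && !allow_override) {
        abort(paste0("refusing to override printed constant '", nm,
                     "' without allow_override = TRUE"))
      }
      base[[nm]]$value <- setNames(as.numeric(val), names(base[[nm]]$value))
    }
  }
  structure(c(base, .cal_derive(base)), class = "damage_calibration")
}

#' Verify internal consistency of a calibration set
#'
#' Recomputes every anchored and derived constant from the stored base
#' constants and checks agreement within `tol`.
#'
#' @param cal A `damage_calibration` object.
#' @param tol Absolute tolerance.
#' @return `TRUE` invisibly, or an error naming the first inconsistent entry.
#' @export
check_calibration <- function(cal, tol = 1e-9) {
  stopifnot(inherits(cal, "damage_calibration"))
  base_names <- names(.cal_base())
  fresh <- .cal_derive(cal[base_names])
  for (nm in names(fresh)) {
    d <- max(abs(as.numeric(fresh[[nm]]$value) - as.numeric(cal[[nm]]$value)))
    if (!is.finite(d) || d > tol) {
      abort(sprintf("calibration entry '%s' inconsistent with its anchors (|diff| = %g)", nm, d))
    }
  }
  invisible(TRUE)
}

#' Write a results table to CSV or JSON
#'
#' Deterministic column order and 6-significant-digit numeric formatting; the
#' JSON form mirrors the CSV fields record by record.
#'
#' @param records A non-empty data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_outputs <- function(records, path, format = c("csv", "json")) {
  format <- arg_match(format)
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("records must be a non-empty data frame")
  }
  out <- as_tibble(records)
  out[] <- lapply(out, function(col) if (is.numeric(col)) signif(col, 6) else col)
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(out, path, digits = NA, dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
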