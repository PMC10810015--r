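# The semi-empirical lesion model. Per voxel traversal the expected total
# lesion count lambda_p(L) is a quadratic in track-averaged LET, anchored
# exactly (3x3 Vandermonde solve) on printed values per particle; the
# measured yields then decompose lambda into a linear direct part (DNA cation
# radicals), a linear indirect part (water radicals) and the remaining
# LEE-mediated part. DSBs use a quadratic-in-SSB pairing form with a hard
# lambda/2 cap, scaled so each particle produces exactly one DSB at its
# printed minimum LET.

# exact quadratic through three (let, value) points
.solve_quadratic <- function(lets, values) {
  if (anyDuplicated(lets)) abort("anchor LETs must be distinct (singular system)")
  stopifnot(length(lets) == 3, length(values) == 3)
  co <- solve(cbind(lets^2, lets, 1), values)
  c(a = co[1], b = co[2], c = co[3])
}

.lambda_eval <- function(coefs, let) {
  pmax(0, coefs[1] * let^2 + coefs[2] * let + coefs[3])
}

# decomposition of lambda into linear direct, linear indirect and LEE parts.
# Where the clamped quadratic falls below the sum of the linear yield terms
# (very low LET), the linear parts are scaled down proportionally so the
# parts always stay non-negative and sum exactly to lambda.
.decompose_eval <- function(coefs, consts, let) {
  lam <- .lambda_eval(coefs, let)
  lin_direct <- consts$ell * let * consts$f_dir * consts$y_ssb_dir
  lin_indirect <- consts$ell * let * (1 - consts$f_dir) *
    (consts$y_ssb_ind + consts$y_base_ind)
  lin_sum <- lin_direct + lin_indirect
  scale <- ifelse(lin_sum > lam & lin_sum > 0, lam / lin_sum, 1)
  lin_direct <- scale * lin_direct
  lin_indirect <- scale * lin_indirect
  lee <- pmax(0, lam - lin_direct - lin_indirect)
  ssb <- scale * consts$ell * let * (consts$f_dir * consts$y_ssb_dir +
                                       (1 - consts$f_dir) * consts$y_ssb_ind) +
    lee * consts$sb_share
  list(total = lam, lin_direct = lin_direct, lin_indirect = lin_indirect,
       lee = lee, ssb = ssb)
}

# mean SSB count s(L)
.ssb_mean_eval <- function(coefs, consts, let) {
  .decompose_eval(coefs, consts, let)$ssb
}

.lesion_consts <- function(cal) {
  list(
    ell = cal_value(cal, "voxel_side_nm"),
    f_dir = cal_value(cal, "direct_fraction"),
    y_ssb_dir = cal_value(cal, "yield_ssb_direct_per_ev"),
    y_ssb_ind = cal_value(cal, "yield_ssb_indirect_per_ev"),
    y_base_ind = cal_value(cal, "yield_base_indirect_per_ev"),
    sb_share = cal_value(cal, "lee_sb_share")
  )
}

.lambda_coef <- function(cal, particle) {
  cal_value(cal, paste0("lambda_coef_", particle))
}

#' Fit the total-lesion quadratic through three anchors
#'
#' Solves the 3x3 Vandermonde system exactly, so every anchor is reproduced
#' to machine precision. This is the calibration route used for the built-in
#' per-particle coefficients; it is exposed so alternative anchor sets (for
#' example a fit restricted to published cluster sizes) can be explored.
#'
#' @param anchors A data frame with columns `let` (keV/um) and `lesions`
#'   (mean total lesions per traversal), exactly three rows with distinct
#'   LETs.
#' @param particle Optional label carried on the result.
#' @return An object of class `lesion_fit` with elements `particle`,
#'   `coefficients` (a, b, c) and `anchors`.
#' @seealso [tidy.lesion_fit()], [mean_lesions()]
#' @export
#' @examples
#' fit <- calibrate_lesion_model(
#'   data.frame(let = c(162.4, 103.4, 11.5), lesions = c(39.8, 23.1, 2.0)),
#'   particle = "alpha"
#' )
#' tidy(fit)
calibrate_lesion_model <- function(anchors, particle = NA_character_) {
  stopifnot(is.data.frame(anchors), all(c("let", "lesions") %in% names(anchors)))
  if (nrow(anchors) != 3) abort("exactly three anchors are required")
  co <- .solve_quadratic(anchors$let, anchors$lesions)
  structure(list(particle = particle, coefficients = co,
                 anchors = as_tibble(anchors)),
            class = "lesion_fit")
}

#' @export
print.lesion_fit <- function(x, ...) {
  cat("<lesion_fit> ", if (is.na(x$particle)) "" else paste0(x$particle, ": "),
      sprintf("lambda(L) = max(0, %.4g L^2 + %.4g L + %.4g)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]), sep = "")
  invisible(x)
}

#' Tidy and glance methods for lesion fits
#'
#' @param x A `lesion_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`term`, `estimate`);
#'   `glance()`: a one-row tibble with the anchor count, LET span and the
#'   maximum absolute residual at the anchors.
#' @export
tidy.lesion_fit <- function(x, ...) {
  tibble(term = c("let^2", "let", "intercept"),
         estimate = unname(x$coefficients))
}

#' @rdname tidy.lesion_fit
#' @export
glance.lesion_fit <- function(x, ...) {
  resid <- .lambda_eval(x$coefficients, x$anchors$let) - x$anchors$lesions
  tibble(n_anchors = nrow(x$anchors),
         let_min = min(x$anchors$let), let_max = max(x$anchors$let),
         max_abs_residual = max(abs(resid)))
}

#' Predict from a lesion fit
#'
#' @param object A `lesion_fit`.
#' @param let_track_avg LET grid in keV/um.
#' @param ... Unused.
#' @return Mean lesion counts (clamped at zero).
#' @export
predict.lesion_fit <- function(object, let_track_avg, ...) {
  .lambda_eval(object$coefficients, let_track_avg)
}

#' Mean total lesions per voxel traversal
#'
#' Evaluates the per-particle anchored quadratic `lambda_p(L)`, clamped at
#' zero (the proton and alpha intercepts are slightly negative, so the raw
#' quadratic dips below zero at very low LET).
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param let_track_avg Track-averaged LET in keV/um, in \[0, 300\];
#'   vectorised.
#' @param cal A calibration set.
#' @return Mean lesions per traversal.
#' @export
#' @examples
#' mean_lesions("alpha", 162.4) # 39.8
mean_lesions <- function(particle, let_track_avg, cal = calibration_set()) {
  .check_particle(particle)
  .check_let(let_track_avg)
  .lambda_eval(.lambda_coef(cal, particle), let_track_avg)
}

#' Decompose the lesion mean into mechanistic parts
#'
#' The linear direct part is the DNA cation-radical SSB term
#' `ell * L * f_dir * Y_SSB,dir`; the linear indirect part is the water-
#' radical term `ell * L * (1 - f_dir) * (Y_SSB,ind + Y_base,ind)`; whatever
#' the quadratic mean exceeds those by is attributed to LEEs. The SSB mean
#' `s(L)` collects the strand-break fractions of all three parts; the base
#' mean is the remainder. Parts are non-negative and sum exactly to the total:
#' at very low LET, where the clamped quadratic falls below the linear yield
#' terms, the linear parts are scaled down proportionally to preserve both
#' properties.
#'
#' @inheritParams mean_lesions
#' @return A tibble with columns `particle`, `let`, `direct_linear`,
#'   `indirect_linear`, `lee`, `ssb_mean`, `base_mean`, `total`.
#' @export
decompose_lesions <- function(particle, let_track_avg, cal = calibration_set()) {
  .check_particle(particle)
  .check_let(let_track_avg)
  consts <- .lesion_consts(cal)
  coefs <- .lambda_coef(cal, particle)
  d <- .decompose_eval(coefs, consts, let_track_avg)
  tibble(particle = particle, let = let_track_avg,
         direct_linear = d$lin_direct, indirect_linear = d$lin_indirect,
         lee = d$lee, ssb_mean = d$ssb, base_mean = d$total - d$ssb,
         total = d$total)
}

#' Mean DSB count per voxel traversal
#'
#' Opposite-strand pairing of SSBs gives a quadratic-in-SSB form,
#' `min(k_D * s(L)^2 / 4, lambda(L) / 2)`, with `k_D` anchored so the value
#' is exactly one at the particle's printed minimum DSB LET, and a hard cap
#' at half the total lesions (two lesions are consumed per DSB; an uncapped
#' quadratic would exceed the total at high LET).
#'
#' @inheritParams mean_lesions
#' @return Mean DSBs per traversal.
#' @export
#' @examples
#' mean_dsb("alpha", 15.2) # 1.0
mean_dsb <- function(particle, let_track_avg, cal = calibration_set()) {
  .check_particle(particle)
  .check_let(let_track_avg)
  consts <- .lesion_consts(cal)
  coefs <- .lambda_coef(cal, particle)
  s <- .ssb_mean_eval(coefs, consts, let_track_avg)
  kd <- cal_value(cal, "dsb_scale", particle)
  pmin(kd * s^2 / 4, .lambda_eval(coefs, let_track_avg) / 2)
}

#' Minimum LET reaching a damage level
#'
#' Bisection root of `quantity(L) = level` on a fixed bracket, after
#' asserting that the quantity is non-decreasing across the bracket grid.
#' Reproduces the clustered-damage onsets (`total_lesions = 2`) and the
#' one-DSB thresholds (`dsb = 1`).
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param quantity `"total_lesions"` or `"dsb"`.
#' @param level Target level; must be attainable on the bracket.
#' @param bracket LET bracket in keV/um.
#' @param tol Absolute tolerance on LET.
#' @param cal A calibration set.
#' @return The threshold LET in keV/um.
#' @export
#' @examples
#' min_let_for("alpha", "total_lesions", 2) # 11.5
#' min_let_for("proton", "dsb", 1)          # 11.8
min_let_for <- function(particle, quantity = c("total_lesions", "dsb"), level,
                        bracket = c(0.1, 300), tol = 1e-3,
                        cal = calibration_set()) {
  quantity <- arg_match(quantity)
  .check_particle(particle)
  f <- switch(quantity,
    total_lesions = function(L) mean_lesions(particle, L, cal),
    dsb = function(L) mean_dsb(particle, L, cal)
  )
  grid <- seq(bracket[1], bracket[2], length.out = 200)
  if (any(diff(f(grid)) < -1e-9)) {
    abort(paste0(quantity, " is not monotone on the bracket; bisection invalid"))
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo) - level; fhi <- f(hi) - level
  if (flo > 0 || fhi < 0) {
    abort(sprintf("level %g not attainable for %s on [%g, %g]",
                  level, quantity, bracket[1], bracket[2]))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) - level <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sample stochastic per-voxel lesion tallies
#'
#' One traversal draws a Poisson total with mean `lambda_scale * lambda(L)`,
#' classifies each lesion as strand break or base lesion with the mean SSB
#' share `s/lambda`, assigns strand breaks to the two strands by fair coin,
#' and counts paired DSBs as the smaller of the two strand tallies (each
#' opposite-strand pair forms one DSB). Reproducible for a given `seed`.
#'
#' @inheritParams mean_lesions
#' @param n Number of independent traversals.
#' @param seed Optional integer seed.
#' @param lambda_scale Scale on the lesion mean (used for partial chords in
#'   the nucleus simulation).
#' @return A tibble with one row per draw: `draw`, `ssb`, `base`, `dsb`,
#'   `total`, plus the deterministic decomposition columns `direct_linear`,
#'   `indirect_linear`, `lee` (recycled).
#' @export
sample_voxel_damage <- function(particle, let_track_avg, n = 1, seed = NULL,
                                lambda_scale = 1, cal = calibration_set()) {
  stopifnot(length(let_track_avg) == 1, n >= 0, lambda_scale >= 0)
  parts <- decompose_lesions(particle, let_track_avg, cal)
  lam <- parts$total
  p_ssb <- if (lam > 0) parts$ssb_mean / lam else 0
  .with_seed(seed, {
    total <- rpois(n, lambda_scale * lam)
    ssb <- rbinom(n, total, p_ssb)
    strand1 <- rbinom(n, ssb, 0.5)
    dsb <- pmin(strand1, ssb - strand1)
    tibble(draw = seq_len(n), ssb = ssb, base = total - ssb, dsb = dsb,
           total = total,
           direct_linear = parts$direct_linear,
           indirect_linear = parts$indirect_linear, lee = parts$lee)
  })
}

#' Deterministic lesion scan over an LET grid
#'
#' @param particle `"electron"`, `"proton"` or `"alpha"`.
#' @param let_track_avg LET grid in keV/um.
#' @param cal A calibration set.
#' @return A tibble of class `lesion_scan` with columns `particle`, `let`,
#'   `total`, `ssb`, `base`, `dsb`.
#' @export
lesion_scan <- function(particle, let_track_avg = seq(0, 300, by = 1),
                        cal = calibration_set()) {
  out <- purrr::map(particle, function(p) {
    d <- decompose_lesions(p, let_track_avg, cal)
    tibble(particle = p, let = let_track_avg, total = d$total,
           ssb = d$ssb_mean, base = d$base_mean,
           dsb = mean_dsb(p, let_track_avg, cal))
  }) |> purrr::list_rbind()
  class(out) <- c("lesion_scan", class(out))
  out
}
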