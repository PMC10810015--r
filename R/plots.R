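# ggplot2 views of the result tables. Figures are conveniences, not
# acceptance surfaces.

#' Plot a lesion scan
#'
#' Mean SSB, base-lesion, DSB and total counts per traversal against LET.
#'
#' @param scan A [lesion_scan()] tibble.
#' @param log_y Log-scale the lesion axis.
#' @return A ggplot object.
#' @export
plot_lesion_scan <- function(scan, log_y = FALSE) {
  long <- tidyr::pivot_longer(scan, c("total", "ssb", "base", "dsb"),
                              names_to = "lesion", values_to = "mean_count")
  p <- ggplot(long, aes(x = .data$let, y = .data$mean_count,
                        colour = .data$lesion)) +
    geom_line() +
    facet_wrap(~particle) +
    labs(x = "track-averaged LET (keV/um)",
         y = "mean lesions per voxel traversal", colour = NULL) +
    theme_minimal()
  if (log_y) p + scale_y_log10() else p
}

#' @export
autoplot.lesion_scan <- function(object, ...) plot_lesion_scan(object, ...)

#' Plot G-value curves
#'
#' @param curves A [g_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_g_curves <- function(curves) {
  ggplot(curves, aes(x = .data$let, y = .data$g, colour = .data$particle)) +
    geom_line() +
    facet_wrap(~species, scales = "free_y") +
    labs(x = "track-averaged LET (keV/um)",
         y = "G-value (molecules per 100 eV) at 100 ns", colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.g_curve <- function(object, ...) plot_g_curves(object)

#' Plot a sampled LEE spectrum
#'
#' @param hist A [lee_spectrum_histogram()] tibble.
#' @return A ggplot object.
#' @export
plot_lee_spectrum <- function(hist) {
  ggplot(hist, aes(x = (.data$bin_low_ev + .data$bin_high_ev) / 2,
                   y = .data$fraction)) +
    geom_col(width = hist$bin_high_ev[1] - hist$bin_low_ev[1]) +
    labs(x = "LEE energy (eV)", y = "fraction of electrons") +
    theme_minimal()
}

#' @export
autoplot.lee_spectrum_hist <- function(object, ...) plot_lee_spectrum(object)

#' Plot the cluster-size / damage-site trade-off
#'
#' The defining LET-fluence trade-off at fixed dose: cluster size grows with
#' LET while the number of distinct damage sites falls.
#'
#' @param scan A [cluster_scan()] tibble.
#' @return A ggplot object.
#' @export
plot_cluster_tradeoff <- function(scan) {
  long <- tidyr::pivot_longer(scan, c("cluster_size", "damage_sites"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$let, y = .data$value, colour = .data$particle)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "track-averaged LET (keV/um)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.cluster_scan <- function(object, ...) plot_cluster_tradeoff(object)
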