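#' Plot density-conditioned movement curves
#'
#' Observed leaving and arrival probabilities against feeder density, with
#' the jackknife variability envelope as a shaded band, the theoretical
#' asocial prediction (TASP) as a solid line, and dashed reference lines at
#' the no-collective-behaviour values (density 0.25, probability 0.25).
#'
#' @param curve A `density_curve`.
#' @param envelope Optional envelope table from [jackknife_envelope()].
#' @param tasp Optional `tasp_curve` (default: computed at the bin mids).
#' @return A ggplot object (leaving and arrival panels).
#' @export
plot_density_curves <- function(curve, envelope = NULL, tasp = NULL) {
  stopifnot(inherits(curve, "density_curve"))
  if (is.null(tasp)) tasp <- tasp_curves(curve$bin_mid)
  long <- rbind(
    data.frame(panel = "leaving", rho = curve$bin_mid, p = curve$p_leave,
               n = curve$n_leave, tasp = tasp$p_leave,
               lo = if (is.null(envelope)) NA_real_ else envelope$leave_lo,
               hi = if (is.null(envelope)) NA_real_ else envelope$leave_hi),
    data.frame(panel = "arriving", rho = curve$bin_mid, p = curve$p_arrive,
               n = curve$n_arrive, tasp = tasp$p_arrive,
               lo = if (is.null(envelope)) NA_real_ else envelope$arrive_lo,
               hi = if (is.null(envelope)) NA_real_ else envelope$arrive_hi)
  )
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0.25, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = .data$tasp), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = .data$p), na.rm = TRUE) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "proportion of patch at feeder (ρ)",
                  y = "probability") +
    ggplot2::theme_bw()
  if (!is.null(envelope)) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
      alpha = 0.25, fill = "steelblue", na.rm = TRUE)
  }
  gg
}

#' Plot a choice-probability surface
#'
#' Probability of choosing the focal feeder over combinations of conspecific
#' and heterospecific counts at that feeder, with the P = 0.25 contour (the
#' threshold above which a site is chosen more often than at random).
#'
#' @param surface A `flock_surface` from [choice_surface()].
#' @return A ggplot object.
#' @export
plot_choice_surface <- function(surface) {
  stopifnot(inherits(surface, "flock_surface"))
  gg <- ggplot2::ggplot(surface$grid,
                        ggplot2::aes(x = .data$n_c, y = .data$n_h,
                                     fill = .data$p_choose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "P(choose x)") +
    ggplot2::labs(x = "conspecifics at feeder x",
                  y = "heterospecifics at feeder x") +
    ggplot2::theme_bw()
  for (seg in surface$contour_25) {
    gg <- gg + ggplot2::geom_path(
      data = seg, ggplot2::aes(x = .data$n_c, y = .data$n_h),
      inherit.aes = FALSE, colour = "black", linewidth = 0.8)
  }
  gg
}
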