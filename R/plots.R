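#' @export
autoplot.angular_histogram <- function(object, ...) {
  fit <- tryCatch(fit_hg(object), error = function(e) NULL)
  p <- ggplot2::ggplot(object$histogram,
                       ggplot2::aes(x = .data$angle_deg, y = .data$weight)) +
    ggplot2::geom_col(width = diff(object$histogram$angle_deg[1:2]),
                      fill = "grey70") +
    ggplot2::labs(x = "exit angle (deg)", y = "photon weight",
                  title = "Monte Carlo goniometry (scattered photons)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = fit$data, ggplot2::aes(y = .data$fitted),
      colour = "firebrick", linewidth = 0.8
    ) +
      ggplot2::labs(subtitle = sprintf("HG fit: g_ef = %.3f", fit$g_ef))
  }
  p
}

#' @export
autoplot.fb_profile <- function(object, ...) {
  d <- object[object$valid, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth_um, y = .data$fb_measured)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fb_measured - .data$fb_se,
      ymax = .data$fb_measured + .data$fb_se
    )) +
    ggplot2::labs(x = "depth (um)", y = "measured F/B",
                  title = "Depth-resolved SHG F/B")
}

#' @export
autoplot.creation_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$depth_um, y = .data$fb_measured)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$fb_measured - .data$fb_se,
      ymax = .data$fb_measured + .data$fb_se
    )) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fb_simulated_best),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(
      x = "depth (um)", y = "F/B",
      title = sprintf("Creation-ratio fit: F_SHG/B_SHG = %.2f", object$fb_creation),
      subtitle = sprintf("reduced chi-squared = %.3g", object$reduced_chi2)
    )
}

#' @export
autoplot.wm_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wavelength_nm,
                                  y = exp(.data$log_mus_reduced))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(
      y = object$amplitude * .data$wavelength_nm^object$spectral_exponent
    ), colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "wavelength (nm)", y = "reduced scattering (1/cm)",
      title = sprintf("Whittle-Matern spectral fit: m = %.2f", object$m)
    )
}

#' Tile plot of the per-patch F/B map
#'
#' @param x A `patch_map` from [measure_fb_patches()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_patch_map <- function(x, ...) {
  stopifnot(inherits(x, "patch_map"))
  ggplot2::ggplot(x$patch_fb, ggplot2::aes(x = .data$patch_col,
                                           y = .data$patch_row,
                                           fill = .data$fb)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "patch column", y = "patch row", fill = "F/B",
                  title = sprintf("Per-patch F/B (%d px patches)", x$patch_size))
}

#' @export
autoplot.cd_result <- function(object, ...) {
  d <- tidyr::expand_grid(row = seq_len(nrow(object$cd_map)),
                          col = seq_len(ncol(object$cd_map)))
  d$cd <- as.vector(t(object$cd_map))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$cd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "CD", title = sprintf(
      "SHG-CD map (mean |CD| = %.3f)", object$mean_abs_cd
    ))
}
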