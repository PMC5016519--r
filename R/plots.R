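#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type: a
#' density map as a filled tile raster, a calibration curve as mean track
#' length versus tracking radius with the plateau marked, a Ripley curve or
#' envelope as h(d) with its interval ribbon, and a localization table as a
#' scatter of coordinates.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name stormquant-autoplot
NULL

#' @rdname stormquant-autoplot
#' @export
autoplot.density_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression("loc/" * mu * m^2)) +
    ggplot2::labs(x = "x (nm)", y = "y (nm)",
                  title = sprintf("Sliding-window density (diameter %g nm, step %g nm)",
                                  attr(object, "diameter"), attr(object, "step")))
}

#' @rdname stormquant-autoplot
#' @param plateau_radius Radius (nm) to mark on a calibration curve.
#' @export
autoplot.calibration_curve <- function(object, plateau_radius = 50, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$radius, .data$mean_track_length)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = plateau_radius, linetype = "dashed") +
    ggplot2::labs(x = "tracking radius (nm)", y = "mean track length (loc/track)",
                  title = "Radius sweep: localization grouping saturation")
}

#' @rdname stormquant-autoplot
#' @export
autoplot.blink_calibration <- function(object, ...) {
  autoplot.calibration_curve(object$curve, plateau_radius = object$plateau_radius) +
    ggplot2::annotate("point", x = object$plateau_radius, y = object$conversion_factor) +
    ggplot2::labs(subtitle = sprintf("conversion factor %.2f +/- %.2f loc/fluorophore; sigma = (%.2f, %.2f) nm",
                                     object$conversion_factor, object$conversion_se,
                                     object$sigma_x, object$sigma_y))
}

#' @rdname stormquant-autoplot
#' @export
autoplot.ripley_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$d, .data$h)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "d (nm)", y = "h(d) (nm)", title = "Ripley's h function")
}

#' @rdname stormquant-autoplot
#' @export
autoplot.ripley_envelope <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$d, .data$mean_h)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "d (nm)", y = "h(d) (nm)",
                  title = sprintf("Ripley's h, mean and %.0f%% CI over %d replicates",
                                  100 * attr(object, "level"), attr(object, "r")))
}

#' @rdname stormquant-autoplot
#' @export
autoplot.loc_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.2, alpha = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' Overlay observed and null Ripley envelopes
#'
#' The standard comparison figure: observed envelope against the CSR
#' (Poisson) and Neyman-Scott nulls on one set of axes.
#'
#' @param observed,csr,ns `ripley_envelope` objects on a shared grid (`ns`
#'   optional).
#' @return A ggplot.
#' @export
plot_ripley_comparison <- function(observed, csr, ns = NULL) {
  lab <- function(env, label) dplyr::mutate(tidy(env), model = label)
  dat <- dplyr::bind_rows(lab(observed, "observed"), lab(csr, "Poisson (CSR)"),
                          if (!is.null(ns)) lab(ns, "Neyman-Scott"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$d, .data$mean_h, colour = .data$model,
                                    fill = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "d (nm)", y = "h(d) (nm)",
                  title = "Observed spatial statistics against null models")
}
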