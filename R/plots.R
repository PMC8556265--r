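# ggplot2 visualisations ------------------------------------------------------

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_rect
#'   labs autoplot theme_minimal geom_hline annotate
NULL

#' Plot a pore profile
#'
#' Pore diameter against the axial coordinate, with the narrowest
#' constriction marked.
#'
#' @param object a `pore_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pore_profile <- function(object, ...) {
  mc <- min_constriction(object)
  ggplot(object, aes(x = .data$z, y = .data$diameter)) +
    geom_line() +
    geom_point(data = mc, aes(x = .data$z, y = .data$diameter),
               colour = "red") +
    labs(x = "axial position z (Å)", y = "pore diameter (Å)",
         title = sprintf("Pore profile (min %.2f Å at z = %.1f)",
                         mc$diameter, mc$z)) +
    theme_minimal()
}

#' Plot an axial density profile
#'
#' Density per bin with detected bottleneck intervals shaded.
#'
#' @param object an `axial_density`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.axial_density <- function(object, ...) {
  bn <- attr(object, "bottlenecks")
  p <- ggplot(object, aes(x = .data$z, y = .data$density)) +
    geom_col(width = diff(object$z[1:2] %||% c(0, 1))) +
    labs(x = "axial position z (Å)", y = "mean count per frame") +
    theme_minimal()
  if (!is.null(bn) && nrow(bn) > 0) {
    p <- p + geom_rect(data = bn,
                       aes(xmin = .data$z_start, xmax = .data$z_end),
                       ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
                       inherit.aes = FALSE)
  }
  p
}

#' Plot a lattice-translocation-defect fit
#'
#' Per-phase-class mean intensities with the fitted cosine modulation.
#'
#' @param object an `ltd_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ltd_fit <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$phase)) +
    geom_point(aes(y = .data$mean_intensity, size = .data$n)) +
    geom_line(aes(y = .data$fitted), colour = "blue") +
    labs(x = expression(h %.% t[d] ~ "mod 1"),
         y = "mean intensity",
         title = sprintf("t_d = (%s), kappa = %.3f",
                         paste(signif(object$model$t_d, 4), collapse = ", "),
                         object$model$kappa)) +
    theme_minimal()
}

#' Plot a site-occupancy history
#'
#' Occupied/vacant state per frame, coloured by occupant identity.
#'
#' @param object an `occupancy_stats`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.occupancy_stats <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$frame, y = as.integer(.data$occupied),
                colour = factor(.data$occupant))) +
    geom_point(size = 0.5, show.legend = FALSE) +
    labs(x = "frame", y = "occupied",
         title = sprintf("%s: occupancy %.1f%%", object$label,
                         100 * object$occupancy)) +
    theme_minimal()
}
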