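#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial distribution function
#'
#' g(r) with the running coordination number on a secondary panel-free
#' overlay (dashed).
#'
#' @param object An `rdf_result` from [compute_rdf()].
#' @param show_coordination Overlay n(r) (rescaled) as a dashed line?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rdf_result <- function(object, show_coordination = FALSE, ...) {
  ps <- attr(object, "pair_spec")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted", alpha = 0.6) +
    ggplot2::labs(x = "r (nm)", y = "g(r)",
                  title = sprintf("RDF %s - %s", ps["a"], ps["b"]))
  if (show_coordination && max(object$coordination) > 0) {
    scale <- max(object$g) / max(object$coordination)
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$coordination * scale), linetype = "dashed")
  }
  p
}

#' Plot a binned pull-force curve with its adhesion dip
#'
#' @param object An `adhesion_result` from [extract_adhesion()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.adhesion_result <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$distance, y = .data$mean_force)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$plateau_force,
                        linetype = "dashed", alpha = 0.6) +
    ggplot2::labs(x = "distance (nm)", y = "binned mean force (nN)",
                  subtitle = sprintf("adhesion force %.3f nN",
                                     object$adhesion_force))
}

#' Plot a PMF curve with its bootstrap uncertainty band
#'
#' @param object A `pmf_curve` from [wham_pmf()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pmf_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$pmf)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pmf - .data$std,
                                      ymax = .data$pmf + .data$std),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "PMF (kJ/mol)")
}

#' Plot per-species number-density profiles
#'
#' @param object A `density_profile` from [density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$density,
                                       color = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = expression(density ~ (nm^-3)))
}

#' Plot the bound-ion count time series
#'
#' @param object A `bound_series` from [bound_count_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bound_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$n_bound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "bound ions",
                  subtitle = sprintf("converged: %s (half-window mean diff %.2f)",
                                     attr(object, "converged"),
                                     attr(object, "half_mean_diff")))
}

#' Bar chart of the motif histogram
#'
#' @param object A `binding_stats` from [binding_statistics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_stats <- function(object, ...) {
  h <- object$motif_histogram
  h$category <- stats::reorder(h$category, -h$mean_ions)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$category, y = .data$mean_ions)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "binding motif", y = "mean ions")
}

#' Plot charge density, field and potential profiles
#'
#' @param object A `potential_profile` from [electrostatic_potential()].
#' @param ... Unused.
#' @return A ggplot (faceted by quantity).
#' @export
autoplot.potential_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rho", "field", "psi"),
                              names_to = "quantity")
  long$quantity <- factor(long$quantity, levels = c("rho", "field", "psi"),
                          labels = c("rho (e/nm^3)", "E (V/nm)", "psi (V)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$z, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "z (nm)", y = NULL)
}
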