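#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return One row per component: `component`, `lifetime_us`, `lifetime_se`,
#'   `amplitude`, `amplitude_se`, `fraction_pct` (amplitude convention).
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  dplyr::left_join(
    x$components,
    molecular_fractions(x)[, c("component", "fraction_pct")],
    by = "component")[, c("component", "lifetime_us", "lifetime_se",
                          "amplitude", "amplitude_se", "fraction_pct")]
}

#' Glance at a decay fit
#'
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_components`, `n_obs`, `baseline`,
#'   `reduced_chi_square`, `residual_runs_p`, `degenerate`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$components), n_obs = x$n_obs,
                 baseline = x$baseline,
                 reduced_chi_square = x$reduced_chi_square,
                 residual_runs_p = x$residual_runs_p,
                 degenerate = x$degenerate)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> '%s': %d component(s), %d samples\n",
              x$label, nrow(x$components), x$n_obs))
  print(tidy(x))
  cat(sprintf("reduced chi-square %.3g, residual runs p = %.3g%s\n",
              x$reduced_chi_square, x$residual_runs_p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Plot a decay fit
#'
#' Data, fitted curve and residuals on a shared time axis.
#'
#' @param object A `decay_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- dplyr::mutate(object$data, fitted = object$fitted,
                      residual = object$residuals)
  long <- tidyr::pivot_longer(df, c("intensity", "residual"),
                              names_to = "panel", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_us, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = dplyr::mutate(df, panel = "intensity",
                                            value = .data$fitted),
                       color = "red3") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (µs)", y = NULL,
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Tidy a binding fit
#'
#' @param x A `binding_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std_error`.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) x$parameters

#' Glance at a binding fit
#'
#' @param x A `binding_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `classification`, `saturation_x`, `n_obs`,
#'   `rss`.
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(classification = x$classification,
                 saturation_x = x$saturation_x,
                 n_obs = nrow(x$data),
                 rss = sum(x$residuals^2))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> %s binding", x$classification))
  if (!is.na(x$saturation_x))
    cat(sprintf(", 95%% saturation at x = %.3g", x$saturation_x))
  cat("\n")
  print(x$parameters)
  invisible(x)
}

#' Plot a binding fit
#'
#' Titration points with the fitted curve and its specific / nonspecific
#' decomposition.
#'
#' @param object A `binding_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  p <- stats::setNames(object$parameters$estimate, object$parameters$term)
  xg <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  spec <- if (object$classification == "specific")
    p[["bmax"]] * xg / (p[["k_half"]] + xg) else rep(0, length(xg))
  curves <- tibble::tibble(
    x = rep(xg, 2),
    value = c(p[["offset"]] + spec + p[["ns_slope"]] * xg,
              p[["offset"]] + p[["ns_slope"]] * xg),
    component = rep(c("total", "nonspecific"), each = length(xg)))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$ratio)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$value,
                                    linetype = .data$component)) +
    ggplot2::labs(x = "lipid load", y = "Tr-FRET ratio") +
    ggplot2::theme_minimal()
}

#' Tidy an occupancy profile
#'
#' @param x An `occupancy_profile` object.
#' @param ... Unused.
#' @return The per-site histogram tibble (`site`, `n_bound`, `pct_frames`).
#' @method tidy occupancy_profile
#' @export
tidy.occupancy_profile <- function(x, ...) x$per_site

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf("<occupancy_profile> %d frames, cutoff %.2f nm, min residues %d\n",
              x$n_frames, x$cutoff, x$min_residues))
  print(x$mean_occupancy)
  invisible(x)
}

#' Plot an occupancy profile
#'
#' Bound-lipid count histograms per site.
#'
#' @param object An `occupancy_profile` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot occupancy_profile
#' @export
autoplot.occupancy_profile <- function(object, ...) {
  ggplot2::ggplot(object$per_site,
                  ggplot2::aes(x = factor(.data$n_bound),
                               y = .data$pct_frames)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$site)) +
    ggplot2::labs(x = "bound lipids per frame", y = "% of frames") +
    ggplot2::theme_minimal()
}
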