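# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a binding fit
#'
#' @param x An `iface_binding_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy iface_binding_fit
#' @export
tidy.iface_binding_fit <- function(x, ...) {
  tibble(term = names(x$estimate),
         estimate = unname(x$estimate),
         std.error = unname(x$std_error))
}

#' One-row summary of a binding fit
#'
#' @inheritParams tidy.iface_binding_fit
#' @return Tibble with `model`, `n`, `rss`, `sigma` (residual SE) and, when
#'   defined for the model, `EC50`.
#' @method glance iface_binding_fit
#' @export
glance.iface_binding_fit <- function(x, ...) {
  k <- length(x$estimate)
  tibble(model = x$model, n = x$n, rss = x$rss,
         sigma = sqrt(x$rss / max(1, x$n - k)),
         EC50 = x$EC50 %||% NA_real_)
}

#' Observed data with fitted values from a binding fit
#'
#' @inheritParams tidy.iface_binding_fit
#' @return The titration data with a `.fitted` column.
#' @method augment iface_binding_fit
#' @export
augment.iface_binding_fit <- function(x, ...) {
  mutate(x$data, .fitted = x$fitted)
}

#' Plot a binding fit: data points and fitted curve
#'
#' @param object An `iface_binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iface_binding_fit
#' @export
autoplot.iface_binding_fit <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$signal)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#2166ac") +
    ggplot2::labs(x = "titrant concentration (µM)", y = "signal",
                  title = sprintf("%s fit", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a contact prevalence profile
#'
#' Per-residue contact frequency along the sequence, faceted by side (and
#' coloured by chain), the standard way docking-ensemble interface
#' statistics are displayed.
#'
#' @param object An `iface_prevalence` or `iface_averaged` profile.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iface_prevalence
#' @export
autoplot.iface_prevalence <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$freq,
                               fill = .data$chain)) +
    ggplot2::geom_col(position = "identity", alpha = 0.8) +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = "residue number", y = "contact frequency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.iface_prevalence
#' @method autoplot iface_averaged
#' @export
autoplot.iface_averaged <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$resno, y = .data$mean,
                                   fill = .data$chain)) +
    ggplot2::geom_col(position = "identity", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                        ymax = pmin(1, .data$mean + .data$sd)),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::facet_wrap(~side, scales = "free_x") +
    ggplot2::labs(x = "residue number", y = "mean contact frequency") +
    ggplot2::theme_minimal()
}

#' Plot a docking funnel
#'
#' Score versus interface RMSD scatter with the best-scoring fraction
#' highlighted; the visual check behind [funnel_analysis()].
#'
#' @param points Data frame with `score` and `irmsd` columns.
#' @param low_fraction Fraction of best-scoring poses to highlight.
#' @return A ggplot.
#' @export
plot_funnel <- function(points, low_fraction = 0.1) {
  n_low <- max(1L, round(nrow(points) * low_fraction))
  pts <- points[order(points$score), , drop = FALSE]
  pts$best <- seq_len(nrow(pts)) <= n_low
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$irmsd, y = .data$score,
                                    colour = .data$best)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "#b2182b"),
                                 name = "best-scoring") +
    ggplot2::labs(x = "interface RMSD (Å)", y = "docking score") +
    ggplot2::theme_minimal()
}

#' Plot an RMSF profile
#'
#' @param object An `iface_rmsf` profile.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iface_rmsf
#' @export
autoplot.iface_rmsf <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$resno, y = .data$rmsf,
                               colour = .data$chain)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue number", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
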