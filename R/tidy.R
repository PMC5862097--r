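#' Turn fitted objects into tidy tibbles
#'
#' `tidy()` returns one row per estimated component; `glance()` a one-row
#' model summary (generics provided here in the broom style).
#'
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.lam_inversion <- function(x, ...) {
  tibble(
    component = c("sensor_identity", sprintf("source_%02d", seq_along(x$gamma))),
    lambda = x$lambda,
    weight = c(exp(x$lambda[1]), x$gamma)
  )
}

#' @rdname tidy
#' @export
glance.lam_inversion <- function(x, ...) {
  tibble(
    scheme = x$scheme,
    free_energy = x$F,
    n_components = length(x$lambda),
    n_spatial_modes = x$n_spatial_modes,
    n_iterations = length(x$F_trace) - 1,
    converged = x$converged,
    variance_explained = x$variance_explained,
    sensor_noise_var = x$sensor_noise_var
  )
}

#' @rdname tidy
#' @export
tidy.lam_sweep <- function(x, ...) x$decisions

#' @rdname tidy
#' @export
glance.lam_sweep <- function(x, ...) x$aggregates

#' Export a decision table to CSV
#'
#' @param sweep a `lam_sweep`.
#' @param path CSV path.
#' @export
write_decisions_csv <- function(sweep, path) {
  utils::write.csv(sweep$decisions, path, row.names = FALSE)
  invisible(path)
}

#' Plot sweep aggregates
#'
#' Accuracy (or pial bias) against SNR per scheme and analysis, in the
#' style of the laminar-discrimination accuracy figures.
#'
#' @param object a `lam_sweep`.
#' @param metric `"accuracy"`, `"pial_bias"`, `"significant_fraction"` or
#'   `"accuracy_thresholded"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lam_sweep <- function(object, metric = "accuracy", ...) {
  agg <- object$aggregates
  if (!"snr_db" %in% names(agg)) agg$snr_db <- NA_real_
  agg$snr_plot <- ifelse(is.finite(agg$snr_db), agg$snr_db,
                         min(agg$snr_db[is.finite(agg$snr_db)], na.rm = TRUE) - 25)
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$snr_plot, y = .data[[metric]],
    colour = .data$scheme, linetype = .data$analysis
  )) +
    ggplot2::geom_hline(yintercept = 50, colour = "grey70", linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-trial amplitude SNR (dB)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot per-simulation laminar metrics
#'
#' Strip plot of the decision metric (free-energy difference or ROI t) by
#' true surface, one panel per scheme and analysis.
#'
#' @param sweep a `lam_sweep`.
#' @param snr_db which SNR level to show.
#' @return a ggplot.
#' @export
plot_decision_metrics <- function(sweep, snr_db = -20) {
  d <- sweep$decisions %>%
    filter(.data$snr_db == !!snr_db) %>%
    mutate(metric = ifelse(.data$analysis == "whole_brain",
                           .data$delta_F, .data$roi_t))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$truth, y = .data$metric, colour = .data$truth
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$scheme + .data$analysis, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(pial = "#2166ac", white = "#b2182b")) +
    ggplot2::labs(x = "simulated surface", y = "laminar metric") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
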