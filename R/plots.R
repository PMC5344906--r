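#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a voltage trajectory
#'
#' @param object an `hb_trajectory`.
#' @param ... unused.
#' @return A ggplot of V against time (s).
#' @method autoplot hb_trajectory
#' @export
autoplot.hb_trajectory <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t / 1000, y = .data$V)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "V (mV)") +
    ggplot2::theme_minimal()
}

#' Log-distance stretching profile of an ISI Lyapunov fit
#'
#' One line per embedding dimension; the slope is the exponent estimate.
#'
#' @param object an `hb_isile`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot hb_isile
#' @export
autoplot.hb_isile <- function(object, ...) {
  adv <- object$config$advance
  df <- purrr::imap_dfr(object$profiles, function(p, nm)
    tibble::tibble(m = nm, step = 0:adv, log_distance = p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$log_distance,
                                   colour = .data$m)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "steps advanced", y = "mean log distance") +
    ggplot2::theme_minimal()
}

#' Scatter-style ISI bifurcation plot
#'
#' @param data long table from [isi_bifurcation()].
#' @param log_y plot intervals on a log scale (default TRUE).
#' @return A ggplot: every ISI against the swept parameter, colored by the
#'   point's ISI-series Lyapunov exponent.
#' @export
plot_isi_bifurcation <- function(data, log_y = TRUE) {
  g <- ggplot2::ggplot(data, ggplot2::aes(x = .data$value, y = .data$isi,
                                          colour = .data$le)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = unique(data$param), y = "ISI (ms)", colour = "LE") +
    ggplot2::theme_minimal()
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}

#' Heatmap of a 2-axis sweep measure
#'
#' @param data an `hb_sweep` tibble from a 2-axis [run_sweep()].
#' @param x,y axis column names (strings).
#' @param fill measure column name (string), e.g. `"mle"` or `"rate"`.
#' @return A ggplot tile map.
#' @export
plot_sweep_map <- function(data, x, y, fill) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}
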