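#' Plot per-window measure traces
#'
#' One panel per measure/scope, raw trace in grey with a moving average
#' (display only) overlaid and a vertical line at seizure onset.
#'
#' @param traces a [measure_all()] tibble.
#' @param span moving-average span in windows.
#' @param scopes optional scope subset.
#' @return A ggplot object.
#' @export
plot_measure_traces <- function(traces, span = 10, scopes = NULL) {
  if (!is.null(scopes)) {
    traces <- dplyr::filter(traces, .data$scope %in% scopes)
  }
  traces <- traces |>
    dplyr::group_by(.data$scope, .data$measure) |>
    dplyr::arrange(.data$window, .by_group = TRUE) |>
    dplyr::mutate(smooth = moving_average(.data$value, span = span)) |>
    dplyr::ungroup()
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$rel_onset_s, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth), linewidth = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.8) +
    ggplot2::facet_grid(measure ~ scope, scales = "free_y") +
    ggplot2::labs(x = "time relative to seizure onset (s)", y = NULL) +
    ggplot2::theme_bw()
}

#' Plot a link-threshold scan
#'
#' SMD of the global density of links across the threshold grid; points
#' where the SMD is undefined are omitted.
#'
#' @param scan a [threshold_scan()] tibble.
#' @return A ggplot object.
#' @export
plot_threshold_scan <- function(scan) {
  ggplot2::ggplot(dplyr::filter(scan, .data$defined),
                  ggplot2::aes(x = .data$threshold, y = .data$smd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "link threshold", y = "SMD of DoL (pre - ictal)") +
    ggplot2::theme_bw()
}

#' Excitability raster
#'
#' Channels-by-time heat map of the normalised excitability, the customary
#' first look at a recording.
#'
#' @param tr an `excitability_trace`.
#' @param cap values above the cap are clipped for display.
#' @return A ggplot object.
#' @export
plot_excitability <- function(tr, cap = 10) {
  stopifnot(inherits(tr, "excitability_trace"))
  df <- tibble::as_tibble(tr$S_norm, rownames = "channel") |>
    tidyr::pivot_longer(-"channel", names_to = "win", values_to = "S_norm") |>
    dplyr::mutate(window = as.integer(sub("^V", "", .data$win)),
                  rel_onset_s = tr$rel_onset_s[.data$window],
                  channel = factor(.data$channel, levels = rev(rownames(tr$S_norm))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_onset_s, y = .data$channel,
                                   fill = pmin(.data$S_norm, cap))) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 name = "excitability") +
    ggplot2::labs(x = "time relative to seizure onset (s)", y = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an analysis: measure traces over scopes
#'
#' @param object an `ictal_analysis`.
#' @param span moving-average span in windows.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot ictal_analysis
#' @export
autoplot.ictal_analysis <- function(object, span = 10, ...) {
  plot_measure_traces(object$traces, span = span)
}
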