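#' Plot an activity raster as an on/off heatmap
#'
#' Cells on the vertical axis, time in seconds on the horizontal axis;
#' filled tiles mark frames inside a Ca2+ event.
#'
#' @param object A `capnet_raster` from [build_raster()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capnet_raster
#' @export
autoplot.capnet_raster <- function(object, ...) {
  fi <- attr(object, "frame_interval")
  m <- unclass(object)
  d <- tibble(
    cell = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    frame = rep(seq_len(ncol(m)), each = nrow(m)),
    on = as.vector(m)
  ) %>%
    mutate(time_s = (.data$frame - 1) * fi)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$cell,
                                  fill = factor(.data$on))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "darkgreen"),
                               guide = "none") +
    ggplot2::labs(x = "time (s)", y = "cell", title = "Ca2+ activity raster")
}

#' Bar plot of per-cell event frequency
#'
#' @param dynamics Tibble from [compute_dynamics()].
#' @return A ggplot.
#' @export
plot_frequency_bars <- function(dynamics) {
  ggplot2::ggplot(dynamics,
                  ggplot2::aes(x = factor(.data$cell_id), y = .data$frequency)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::labs(x = "cell", y = "events / min",
                  title = "Ca2+ event frequency by cell")
}

#' Plot line-scan blocks shaded by event label with the flux trend
#'
#' @param blocks Labelled tibble from [label_blocks()].
#' @return A ggplot.
#' @export
plot_linescan_blocks <- function(blocks) {
  stopifnot("label" %in% names(blocks))
  d <- blocks %>% mutate(trend = smooth_flux(.data$flux))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$block)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$flux, fill = .data$label),
                      width = 1, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), linewidth = 0.8) +
    ggplot2::scale_fill_manual(values = c(
      no_event = "grey80", before = "steelblue",
      during = "darkgreen", after = "orange"
    )) +
    ggplot2::labs(x = "block", y = "flux (cells/s)", fill = "event phase")
}

#' Plot a normalised extravascular permeability series
#'
#' @param object A `capnet_permeability` from [extravascular_permeability()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot capnet_permeability
#' @export
autoplot.capnet_permeability <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$time_min, y = .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$at_times, colour = "red") +
    ggplot2::labs(x = "minutes post-injection",
                  y = "extravascular MFI (normalised to pre-dextran)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
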