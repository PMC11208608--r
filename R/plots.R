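#' Plot a recording with detected sharp wave-ripple events
#'
#' Shows the raw trace with detected event peaks and boundaries overlaid.
#'
#' @param x An [lfp_recording()].
#' @param events Tibble from [detect_swr()].
#' @param downsample Plot every k-th sample (default: aim for ~20k points).
#' @return A ggplot object.
#' @export
plot_swr_detection <- function(x, events, downsample = NULL) {
  stopifnot(inherits(x, "lfp_recording"))
  t <- lfp_time(x)
  if (is.null(downsample)) {
    downsample <- max(1L, floor(length(t) / 20000))
  }
  idx <- seq(1L, length(t), by = downsample)
  df <- tibble(time = t[idx], uv = x$samples[idx])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "LFP (µV)") +
    ggplot2::theme_minimal()
  if (nrow(events)) {
    p <- p +
      ggplot2::geom_vline(data = events,
                          ggplot2::aes(xintercept = .data$peak_time),
                          colour = "firebrick", alpha = 0.6,
                          linewidth = 0.3) +
      ggplot2::geom_rect(data = events, inherit.aes = FALSE,
                         ggplot2::aes(xmin = .data$onset,
                                      xmax = .data$offset,
                                      ymin = -Inf, ymax = Inf),
                         fill = "firebrick", alpha = 0.08)
  }
  p
}

#' Plot paired ATP / microglia-reporter traces
#'
#' @param pair A [recruitment_pair()].
#' @return A ggplot object (ATP dF/F and reporter MFI on free y scales).
#' @export
plot_recruitment_pair <- function(pair) {
  stopifnot(inherits(pair, "recruitment_pair"))
  t <- (seq_along(pair$atp_trace) - 1L) * pair$dt
  df <- dplyr::bind_rows(
    tibble(time = t, value = pair$atp_trace, channel = "ATP sensor (dF/F)"),
    tibble(time = t, value = pair$mg_trace, channel = "microglia reporter (MFI)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$channel),
                       show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = pair$atp_peak_time, linetype = 2,
                        colour = "grey50") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c("forestgreen", "firebrick")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a depth-zone profile
#'
#' @param profile Tibble from [zone_profile()].
#' @return A ggplot bar chart of percent per zone (zone 1 = top).
#' @export
plot_zone_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = factor(.data$zone), y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "zone (1 = top surface)", y = "cell bodies (%)") +
    ggplot2::theme_minimal()
}

#' Plot flash/surge clusters in feature space
#'
#' @param features Labelled feature tibble from [cluster_flash_surge()].
#' @return A ggplot of log peak intensity vs log duration, point size by
#'   area, coloured by class.
#' @export
plot_flash_surge <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = log10(.data$duration),
                               y = log10(.data$peak),
                               size = .data$area,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(
      values = c(flash = "goldenrod", surge = "firebrick",
                 unassigned = "grey60")) +
    ggplot2::labs(x = "log10 duration (s)", y = "log10 peak intensity",
                  colour = "class", size = "area") +
    ggplot2::theme_minimal()
}

#' Calibration curve plot
#'
#' @param object An [calibrate_concentration()] object.
#' @param ... Unused.
#' @return A ggplot of intensity vs concentration with the fitted line.
#' @export
autoplot.atp_calibration <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$concentration,
                               y = .data$intensity)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(x = "[ATP] (M)", y = "mean intensity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
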