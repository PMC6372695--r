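#' Relative-frequency curvature (or torsion) profiles per case
#'
#' Step profiles of the per-case relative frequency in fixed-width bins,
#' one line per case.
#'
#' @param per_segment Per-segment geometry tibble.
#' @param parameter `"mean_curvature"` or `"mean_torsion"`.
#' @param bin_width Bin width, micrometres^-1.
#' @return A ggplot object.
#' @export
plot_frequency_profiles <- function(per_segment,
                                    parameter = "mean_curvature",
                                    bin_width = 0.1) {
  dat <- per_segment %>%
    filter(!is.na(.data[[parameter]])) %>%
    group_by(.data$case_id) %>%
    summarise(hist = list(histogram_relative(.data[[parameter]], bin_width)),
              .groups = "drop") %>%
    unnest("hist")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_left + bin_width / 2,
                                    y = .data$frequency,
                                    colour = .data$case_id)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = bquote(.(gsub("mean_", "", parameter)) ~ (mu * m^-1)),
                  y = "relative frequency", colour = "case") +
    ggplot2::theme_minimal()
}

#' Quartile summaries of a geometric parameter per case
#'
#' Violin-free distribution display: median and quartile bars per case,
#' points jittered behind.
#'
#' @inheritParams plot_frequency_profiles
#' @param max_points Jittered points drawn per case (sampled when more).
#' @return A ggplot object.
#' @export
plot_case_distributions <- function(per_segment,
                                    parameter = "mean_curvature",
                                    max_points = 500) {
  dat <- per_segment %>% filter(!is.na(.data[[parameter]]))
  dat <- dat %>%
    group_by(.data$case_id) %>%
    filter(row_number() %in%
             sample(seq_len(n()), min(n(), max_points))) %>%
    ungroup()
  q <- dat %>%
    group_by(.data$case_id) %>%
    summarise(q1 = stats::quantile(.data[[parameter]], 0.25),
              q2 = median(.data[[parameter]]),
              q3 = stats::quantile(.data[[parameter]], 0.75),
              .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$case_id,
                                    y = .data[[parameter]])) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.2, size = 0.4) +
    ggplot2::geom_errorbar(data = q, ggplot2::aes(
      x = .data$case_id, ymin = .data$q1, ymax = .data$q3),
      inherit.aes = FALSE, width = 0.5) +
    ggplot2::geom_point(data = q, ggplot2::aes(x = .data$case_id,
                                               y = .data$q2),
                        inherit.aes = FALSE, shape = 3, size = 2) +
    ggplot2::labs(x = "case") +
    ggplot2::theme_minimal()
}

#' Curvature against fibre radius
#'
#' Mean trajectory curvature of each segment against its mean fibre radius,
#' spiny dendrites and smooth neurites coloured separately; segments with
#' mean radius above `radius_omit` are dropped from the plot (flagged, not
#' dropped, in the report table).
#'
#' @param per_segment Per-segment geometry tibble.
#' @param radius_omit Plot cut-off for the mean radius, micrometres.
#' @return A ggplot object.
#' @export
plot_curvature_radius <- function(per_segment, radius_omit = 3) {
  dat <- per_segment %>%
    filter(!is.na(.data$mean_curvature), .data$mean_radius <= radius_omit)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_radius,
                                    y = .data$mean_curvature,
                                    colour = .data$ctype)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = expression(mean ~ radius ~ (mu * m)),
                  y = expression(mean ~ curvature ~ (mu * m^-1)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Spine length against minimum radius (or radius ratio)
#'
#' The length / minimum-radius plane separates stubby spines (short, radius
#' tracking length: a wedge) from necked mushroom spines (long, thin neck: a
#' triangle); outliers are marked, not removed.
#'
#' @param spines Per-spine metrics tibble ([spine_metrics()]).
#' @param y `"min_radius"` or `"radius_ratio"`.
#' @param length_omit,ratio_omit Outlier marking thresholds.
#' @return A ggplot object.
#' @export
plot_spine_scatter <- function(spines, y = "min_radius", length_omit = 6,
                               ratio_omit = 2.7) {
  dat <- spines %>%
    mutate(outlier = .data$length > length_omit |
             (y == "radius_ratio" & !is.na(.data$radius_ratio) &
                .data$radius_ratio > ratio_omit))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$length, y = .data[[y]],
                                    shape = .data$outlier)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = expression(length ~ (mu * m))) +
    ggplot2::theme_minimal()
}
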