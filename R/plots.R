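#' Plot the VP signal stages
#'
#' Raw VP signal with its moving average, and the photoplethysmographic
#' representation below, on a shared time axis.
#'
#' @param object A `vp_signal` tibble from [process_vp_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vp_signal <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("time_s", "i_vp", "i_avg", "i_ppg")],
    c("i_vp", "i_avg", "i_ppg"), names_to = "series")
  df$panel <- ifelse(df$series == "i_ppg", "PPG representation [%]",
                     "ROI mean intensity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an analysed recording
#'
#' The photoplethysmographic signal with detected R-waves (vertical
#' dashed lines) and vein-collapse times (points) overlaid.
#'
#' @param object A `vp_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vp_analysis <- function(object, ...) {
  sig <- as_tibble(object$signal)
  cyc <- dplyr::filter(object$cycles, .data$valid)
  ggplot2::ggplot(sig, ggplot2::aes(.data$time_s, .data$i_ppg)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$r_waves$time_s,
                        linetype = "dashed", colour = "firebrick",
                        alpha = 0.6) +
    ggplot2::geom_point(data = cyc,
                        ggplot2::aes(.data$collapse_time_s,
                                     y = min(sig$i_ppg)),
                        colour = "forestgreen", shape = 17, size = 2) +
    ggplot2::labs(x = "time [s]", y = "PPG signal [%]",
                  title = "R-waves (dashed) and detected vein collapses (triangles)") +
    ggplot2::theme_minimal()
}

#' Per-subject boxplot of collapse times
#'
#' @param cycles Per-cycle tibble with `subject_id` and `tvc_ms` (invalid
#'   cycles dropped if a `valid` column is present).
#' @param relative Plot `tvc_rel_pct` instead of `tvc_ms`.
#' @return A ggplot object.
#' @export
plot_subject_boxplot <- function(cycles, relative = FALSE) {
  if ("valid" %in% names(cycles)) cycles <- dplyr::filter(cycles, .data$valid)
  yvar <- if (relative) "tvc_rel_pct" else "tvc_ms"
  ylab <- if (relative) "T_vc [% of cycle]" else "T_vc [ms]"
  ggplot2::ggplot(cycles, ggplot2::aes(.data$subject_id, .data[[yvar]])) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.5) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Violin plot of the pooled collapse-time distribution
#'
#' @inheritParams plot_subject_boxplot
#' @return A ggplot object.
#' @export
plot_pooled_violin <- function(cycles, relative = FALSE) {
  if ("valid" %in% names(cycles)) cycles <- dplyr::filter(cycles, .data$valid)
  yvar <- if (relative) "tvc_rel_pct" else "tvc_ms"
  ylab <- if (relative) "T_vc [% of cycle]" else "T_vc [ms]"
  ggplot2::ggplot(cycles, ggplot2::aes(x = "all subjects", y = .data[[yvar]])) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Scatter of cycle length against collapse time
#'
#' One dot per cardiac cycle, coloured by subject, with the pooled
#' Spearman correlation in the subtitle.
#'
#' @param cycles Per-cycle tibble with `subject_id`, `rr_s`, `tvc_ms`.
#' @return A ggplot object.
#' @export
plot_cycle_scatter <- function(cycles) {
  cs <- cycle_scatter(cycles)
  ggplot2::ggplot(cs$table, ggplot2::aes(.data$rr_s, .data$tvc_ms,
                                         colour = .data$subject_id)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "cardiac cycle length [s]", y = "T_vc [ms]",
                  colour = "subject",
                  subtitle = sprintf("Spearman rho = %.2f (n = %d cycles)",
                                     cs$correlation$rho, cs$correlation$n)) +
    ggplot2::theme_minimal()
}
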