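# Figure-style plots for simulated sessions and their statistics.

#' Plot eye-speed traces of a session
#'
#' Individual-trial speed traces with the across-trial mean overlaid, for a
#' quick visual check of latency, gain and injected saccades.
#'
#' @param session Preprocessed session tibble (with a `velocity`
#'   list-column).
#' @param max_trials Number of individual trials drawn.
#' @return A ggplot object.
#' @export
plot_session_speed <- function(session, max_trials = 50) {
  idx <- head(seq_len(nrow(session)), max_trials)
  df <- purrr::map_dfr(idx, function(i)
    dplyr::mutate(session$velocity[[i]], trial = session$trial_index[i]))
  avg <- dplyr::summarise(dplyr::group_by(df, .data$time_ms),
                          speed = mean(.data$speed_deg_s), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$speed_deg_s,
                                   group = .data$trial)) +
    ggplot2::geom_line(alpha = 0.2, colour = "grey50") +
    ggplot2::geom_line(data = avg, ggplot2::aes(y = .data$speed, group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "time from motion onset (ms)", y = "eye speed (deg/s)") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved bias and precision curves
#'
#' Bias-ratio and direction-SD timecourses per prior block and contrast,
#' averaged across sessions.
#'
#' @param tc_stats Tibble from [timecourse_statistics()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc_stats) {
  df <- tidyr::pivot_longer(tc_stats, c("bias_ratio", "sd_deg"),
                            names_to = "stat", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$value,
                                   colour = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(stat ~ contrast, scales = "free_y") +
    ggplot2::labs(x = "time from motion onset (ms)", y = NULL,
                  colour = "prior block") +
    ggplot2::theme_minimal()
}
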