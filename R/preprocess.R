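#' Zero-phase low-pass Butterworth filter
#'
#' Applies a second-order low-pass Butterworth filter forward and backward
#' (zero-phase), so signal features are not shifted in time and the DC gain
#' is exactly 1. The effective magnitude response is the squared single-pass
#' response, approximately `1 / (1 + (f/fc)^4)` for a second-order design.
#'
#' @param x Numeric vector sampled uniformly at `fs` Hz.
#' @param cutoff_hz Cut-off frequency, Hz; must be below the Nyquist
#'   frequency.
#' @param order Filter order.
#' @param fs Sampling rate, Hz.
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff_hz = 20, order = 2, fs = 1000) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2, order >= 1)
  n_pad <- 3 * (order + 1)
  if (length(x) < 3 * n_pad)
    stop("trace too short for stable zero-phase filtering")
  bf <- butter_coefs(cutoff_hz, order, fs)
  n <- length(x)
  n_pad <- min(n - 1, max(3 * n_pad, ceiling(3 * fs / cutoff_hz)))
  # odd-symmetric reflection keeps the local trend continuous at both edges
  pad <- c(2 * x[1] - x[(n_pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - n_pad)])
  y <- iir_pass(pad, bf$b, bf$a)
  y <- rev(iir_pass(rev(y), bf$b, bf$a))
  y[(n_pad + 1):(n_pad + n)]
}

# one causal IIR pass initialised at steady state for the first sample, so a
# constant signal passes through exactly unchanged (unit DC gain)
iir_pass <- function(x, b, a) {
  x0 <- x[1]
  xx <- c(rep(x0, length(b) - 1), x)
  z <- as.numeric(stats::filter(xx, b, method = "convolution", sides = 1))
  z <- z[-seq_len(length(b) - 1)]
  as.numeric(stats::filter(z, -a[-1], method = "recursive",
                           init = rep(x0, length(a) - 1)))
}

# cached Butterworth designs (signal::butter is costly relative to filtering)
butter_env <- new.env(parent = emptyenv())
butter_coefs <- function(cutoff_hz, order, fs) {
  key <- paste(cutoff_hz, order, fs)
  if (is.null(butter_env[[key]])) {
    bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
    butter_env[[key]] <- list(b = bf$b, a = bf$a)
  }
  butter_env[[key]]
}

#' Low-pass filter both position components of a trace
#'
#' Convenience wrapper applying [lowpass_filter()] to `eye_h_deg` and
#' `eye_v_deg`.
#'
#' @param trace Position tibble (`time_ms`, `eye_h_deg`, `eye_v_deg`).
#' @inheritParams lowpass_filter
#' @return The trace with filtered positions.
#' @export
filter_positions <- function(trace, cutoff_hz = 20, order = 2, fs = 1000) {
  trace$eye_h_deg <- lowpass_filter(trace$eye_h_deg, cutoff_hz, order, fs)
  trace$eye_v_deg <- lowpass_filter(trace$eye_v_deg, cutoff_hz, order, fs)
  trace
}

#' Differentiate a position trace into velocity
#'
#' Central-difference derivative of the horizontal and vertical eye position,
#' scaled to deg/s; endpoints use one-sided differences. Requires a uniform
#' time base.
#'
#' @param trace Tibble with `time_ms`, `eye_h_deg`, `eye_v_deg`.
#' @return Tibble with `time_ms`, `vel_h_deg_s`, `vel_v_deg_s`,
#'   `speed_deg_s`.
#' @export
differentiate <- function(trace) {
  t <- trace$time_ms
  dt <- diff(t)
  if (length(unique(round(dt, 9))) != 1)
    stop("non-uniform time base")
  fs <- 1000 / dt[1]
  cd <- function(p) {
    n <- length(p)
    v <- numeric(n)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / 2
    v[1] <- p[2] - p[1]
    v[n] <- p[n] - p[n - 1]
    v * fs
  }
  vh <- cd(trace$eye_h_deg)
  vv <- cd(trace$eye_v_deg)
  tibble::new_tibble(list(
    time_ms = t,
    vel_h_deg_s = vh,
    vel_v_deg_s = vv,
    speed_deg_s = sqrt(vh^2 + vv^2)
  ), nrow = length(t))
}

#' Detect saccades in a velocity trace
#'
#' Flags epochs where radial eye speed exceeds a running-median baseline by
#' more than `speed_thresh` for at least `min_dur_ms`. The running median
#' (window `baseline_win_ms`) tracks the smooth pursuit speed, so the
#' criterion is on residual speed and is insensitive to pursuit itself.
#'
#' @param velocity Tibble from [differentiate()].
#' @param speed_thresh Residual speed threshold, deg/s.
#' @param min_dur_ms Minimum supra-threshold duration, ms.
#' @param baseline_win_ms Running-median window, ms.
#' @return Tibble of events: `onset_ms`, `offset_ms`, `peak_speed_deg_s`
#'   (zero rows if none).
#' @export
detect_saccades <- function(velocity, speed_thresh = 30, min_dur_ms = 5,
                            baseline_win_ms = 50) {
  sp <- velocity$speed_deg_s
  t <- velocity$time_ms
  dt <- t[2] - t[1]
  k <- round(baseline_win_ms / dt)
  if (k %% 2 == 0) k <- k + 1
  baseline <- runmed(sp, k, endrule = "median")
  above <- (sp - baseline) > speed_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_dur_ms / dt
  if (!any(keep)) {
    return(tibble::new_tibble(list(onset_ms = numeric(), offset_ms = numeric(),
                                   peak_speed_deg_s = numeric()), nrow = 0L))
  }
  tibble::new_tibble(list(
    onset_ms = t[starts[keep]],
    offset_ms = t[ends[keep]],
    peak_speed_deg_s = purrr::map2_dbl(starts[keep], ends[keep],
                                       ~max(sp[.x:.y]))
  ), nrow = sum(keep))
}

#' Preprocess every trial of a session
#'
#' Low-pass filters the position traces, differentiates them to velocity,
#' and runs saccade detection, adding `velocity` and `saccades` list-columns
#' to the session tibble.
#'
#' @param session Session tibble from [simulate_session()] (or the same
#'   layout read from disk).
#' @param cutoff_hz,order Filter settings, see [lowpass_filter()].
#' @param speed_thresh,min_dur_ms,baseline_win_ms Saccade-detection settings,
#'   see [detect_saccades()].
#' @return The session tibble with `velocity` and `saccades` list-columns.
#' @export
preprocess_session <- function(session, cutoff_hz = 20, order = 2,
                               speed_thresh = 30, min_dur_ms = 5,
                               baseline_win_ms = 50) {
  cfg <- attr(session, "task_config")
  fs <- if (!is.null(cfg)) cfg$sample_rate_hz else 1000
  session$velocity <- purrr::map(session$trace, function(tr) {
    differentiate(filter_positions(tr, cutoff_hz, order, fs))
  })
  session$saccades <- purrr::map(session$velocity, detect_saccades,
                                 speed_thresh = speed_thresh,
                                 min_dur_ms = min_dur_ms,
                                 baseline_win_ms = baseline_win_ms)
  session
}

#' Exclude trials with saccades in the open-loop window
#'
#' Removes every trial with a detected saccade overlapping the (closed)
#' exclusion window, by default -100 to 250 ms from motion onset. The
#' exclusion log is attached as attribute `"exclusion_log"`.
#'
#' @param session Preprocessed session tibble (see [preprocess_session()]).
#' @param window Length-2 numeric, exclusion window in ms from motion onset.
#' @return The kept trials, with an `"exclusion_log"` attribute (tibble of
#'   `trial_index`, `reason`, `onset_ms`, `offset_ms`).
#' @export
exclude_trials <- function(session, window = c(-100, 250)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  hit <- purrr::map_lgl(session$saccades, function(ev) {
    nrow(ev) > 0 && any(ev$onset_ms <= window[2] & ev$offset_ms >= window[1])
  })
  log <- purrr::map_dfr(which(hit), function(i) {
    ev <- session$saccades[[i]]
    ov <- ev[ev$onset_ms <= window[2] & ev$offset_ms >= window[1], ]
    tibble::tibble(trial_index = session$trial_index[i],
                   reason = "saccade_in_window",
                   onset_ms = ov$onset_ms[1], offset_ms = ov$offset_ms[1])
  })
  if (nrow(log) == 0) {
    log <- tibble::tibble(trial_index = integer(), reason = character(),
                          onset_ms = numeric(), offset_ms = numeric())
  }
  kept <- session[!hit, ]
  for (a in c("task_config", "gen_params", "seed"))
    attr(kept, a) <- attr(session, a)
  attr(kept, "exclusion_log") <- log
  kept
}
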