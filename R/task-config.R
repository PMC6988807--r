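#' Task configuration for a two-block pursuit session
#'
#' Describes the block design of the direction-prior pursuit task: a
#' narrow-prior block in which the target moves along the prior direction or
#' the prior direction +/- 15 degrees (the prior direction shown twice as
#' often), and a wide-prior block with three directions 120 degrees apart.
#' A session alternates the two block types `n_block_reps` times each.
#'
#' @param prior_direction Prior (central) direction in degrees; common to both
#'   blocks.
#' @param narrow_offsets Outer-direction offsets of the narrow block, degrees;
#'   must be symmetric about 0.
#' @param wide_offsets Outer-direction offsets of the wide block, degrees;
#'   must be symmetric about 0.
#' @param n_trials_narrow,n_trials_wide Trials per narrow / wide block.
#' @param n_block_reps Number of repeats of each block type per session.
#' @param prior_dir_weight How many times more often the prior direction is
#'   shown than each outer direction in the narrow block (>= 1).
#' @param target_speed Target speed, deg/s.
#' @param local_motion_ms Duration of the initial local (aperture-static)
#'   motion, ms.
#' @param motion_duration_ms Duration of target motion from onset, ms.
#' @param pre_onset_ms Length of fixation epoch retained before motion onset,
#'   ms.
#' @param sample_rate_hz Sampling rate of the eye traces, Hz.
#' @return A list of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials_narrow
#' @export
task_config <- function(prior_direction = 0,
                        narrow_offsets = c(-15, 15),
                        wide_offsets = c(-120, 120),
                        n_trials_narrow = 252,
                        n_trials_wide = 378,
                        n_block_reps = 4,
                        prior_dir_weight = 2,
                        target_speed = 15,
                        local_motion_ms = 100,
                        motion_duration_ms = 600,
                        pre_onset_ms = 300,
                        sample_rate_hz = 1000) {
  stopifnot(
    length(narrow_offsets) == 2, length(wide_offsets) == 2,
    isTRUE(all.equal(sum(narrow_offsets), 0)),
    isTRUE(all.equal(sum(wide_offsets), 0)),
    n_trials_narrow > 0, n_trials_wide > 0, n_block_reps >= 1,
    prior_dir_weight >= 1,
    target_speed > 0, motion_duration_ms > 0, sample_rate_hz > 0
  )
  narrow_dirs <- prior_direction + c(narrow_offsets[1], 0, narrow_offsets[2])
  wide_dirs <- prior_direction + c(wide_offsets[1], 0, wide_offsets[2])
  if (anyDuplicated(wrap_angle(narrow_dirs)) || anyDuplicated(wrap_angle(wide_dirs)))
    stop("direction sets contain duplicated directions")
  structure(list(
    prior_direction = prior_direction,
    narrow_offsets = sort(narrow_offsets),
    wide_offsets = sort(wide_offsets),
    narrow_directions = narrow_dirs,
    wide_directions = wide_dirs,
    n_trials_narrow = n_trials_narrow,
    n_trials_wide = n_trials_wide,
    n_block_reps = n_block_reps,
    prior_dir_weight = prior_dir_weight,
    target_speed = target_speed,
    local_motion_ms = local_motion_ms,
    motion_duration_ms = motion_duration_ms,
    pre_onset_ms = pre_onset_ms,
    sample_rate_hz = sample_rate_hz
  ), class = "task_config")
}

# integer per-direction counts for one block; remainder spread outward
block_direction_counts <- function(config, block) {
  if (block == "narrow") {
    dirs <- config$narrow_directions
    w <- c(1, config$prior_dir_weight, 1)
    n <- config$n_trials_narrow
  } else {
    dirs <- config$wide_directions
    w <- c(1, 1, 1)
    n <- config$n_trials_wide
  }
  counts <- floor(n * w / sum(w))
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1
  tibble::tibble(theta_s = dirs, n = counts)
}

#' Generative observer parameters for synthetic sessions
#'
#' Parameters of the generative model behind [simulate_session()]: on each
#' trial a sensory measurement is drawn around the target direction
#' (`theta_m ~ N(theta_s, sigma_m_eff)`), combined with the Gaussian direction
#' prior of the active block into a MAP estimate, and the eye pursues along
#' that estimate with trial-varying latency and gain. Defaults are the
#' session-average observer parameters of an example animal (likelihood SD
#' 7.94 deg, low-contrast scaling 1.83, narrow-prior SD 34.5 deg, effectively
#' flat wide prior).
#'
#' @param sigma_m_base Likelihood SD at high contrast, degrees; scalar or one
#'   value per direction (recycled across the session's direction set).
#' @param contrast_factor Multiplier on `sigma_m_base` at low contrast (>= 1).
#' @param sigma_p_narrow,sigma_p_wide Prior SD in the narrow / wide block,
#'   degrees.
#' @param motor_noise_sd Additive direction noise downstream of the MAP
#'   estimate, degrees.
#' @param latency_mean_high,latency_mean_low Mean pursuit latency at high /
#'   low contrast, ms.
#' @param latency_sd Across-trial latency SD, ms.
#' @param gain_mean,gain_sd Mean and SD of the trial speed gain
#'   (eye speed / target speed).
#' @param vel_noise_sd White velocity noise added to each velocity component,
#'   deg/s at the raw sampling rate.
#' @param adaptation_shift Degrees by which a trial's pursuit direction is
#'   shifted toward the previous trial's target direction (when the two
#'   directions differ); 0 disables single-trial adaptation.
#' @param saccade_prob Probability that a trial contains one injected saccade
#'   (onset uniform in 0-400 ms from motion onset).
#' @param rise_ms Time for the velocity onset to reach 90% of its asymptote,
#'   ms.
#' @param sigma_m_timecourse Optional `c(amplitude, decay_ms)`: makes the
#'   likelihood SD decay over time within a trial,
#'   `sigma_m(t) = sigma_m * (1 + A * exp(-t / tau))`, so that the pursued
#'   direction relaxes from an early, strongly prior-weighted MAP toward the
#'   final MAP.
#' @return A list of class `"gen_params"`.
#' @export
gen_params <- function(sigma_m_base = 7.94,
                       contrast_factor = 1.83,
                       sigma_p_narrow = 34.5,
                       sigma_p_wide = 1e6,
                       motor_noise_sd = 0,
                       latency_mean_high = 120,
                       latency_mean_low = 160,
                       latency_sd = 15,
                       gain_mean = 1,
                       gain_sd = 0.1,
                       vel_noise_sd = 1,
                       adaptation_shift = 0,
                       saccade_prob = 0.15,
                       rise_ms = 60,
                       sigma_m_timecourse = NULL) {
  stopifnot(
    all(sigma_m_base > 0), contrast_factor >= 1,
    sigma_p_narrow > 0, sigma_p_wide > 0,
    motor_noise_sd >= 0, latency_sd >= 0, gain_sd >= 0,
    vel_noise_sd >= 0, saccade_prob >= 0, saccade_prob <= 1, rise_ms > 0
  )
  if (!is.null(sigma_m_timecourse)) {
    stopifnot(length(sigma_m_timecourse) == 2, sigma_m_timecourse[2] > 0)
  }
  structure(as.list(environment()), class = "gen_params")
}
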