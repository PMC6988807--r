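#' Draw per-trial pursuit directions from the generative observer
#'
#' On each trial the observer measures the target direction with Gaussian
#' noise, `theta_m ~ N(theta_s, sigma_m_eff)`, and combines the measurement
#' with a Gaussian direction prior `N(theta_p, sigma_p)`. The pursued
#' direction is the maximum a posteriori estimate
#' `w * theta_m + (1 - w) * theta_p`, `w = sigma_p^2 / (sigma_p^2 + sigma_m_eff^2)`,
#' plus optional motor noise. Over many draws the sample mean and SD follow
#' the closed-form MAP moments (see [predict_mean_sd()]), with motor variance
#' adding in quadrature.
#'
#' @param theta_s True stimulus direction, degrees.
#' @param theta_p Prior mean direction, degrees.
#' @param sigma_m_eff Effective likelihood SD, degrees (> 0).
#' @param sigma_p Prior SD, degrees (> 0).
#' @param motor_noise_sd Additive motor direction noise SD, degrees.
#' @param n Number of trials to draw.
#' @return Numeric vector of `n` pursuit directions, degrees.
#' @examples
#' withr::with_seed(1, {
#'   d <- sample_trial_direction(15, 0, sigma_m_eff = 14.53, sigma_p = 34.5,
#'                               n = 1e4)
#'   c(mean(d), sd(d)) # close to the MAP-moment predictions 12.74, 12.34
#' })
#' @export
sample_trial_direction <- function(theta_s, theta_p, sigma_m_eff, sigma_p,
                                   motor_noise_sd = 0, n = 1) {
  if (!is.numeric(sigma_m_eff) || sigma_m_eff <= 0)
    stop("sigma_m_eff must be > 0")
  if (!is.numeric(sigma_p) || sigma_p <= 0)
    stop("sigma_p must be > 0")
  stopifnot(motor_noise_sd >= 0, n >= 1)
  theta_m <- rnorm(n, theta_s, sigma_m_eff)
  est <- map_estimate(theta_m, theta_p, sigma_m_eff, sigma_p)
  if (motor_noise_sd > 0) est <- est + rnorm(n, 0, motor_noise_sd)
  est
}

# time for the half-logistic onset to reach 90% of asymptote is rise_ms:
# 2/(1+exp(-x)) - 1 = 0.9  =>  x = log(19)
onset_profile <- function(t_from_latency, rise_ms) {
  s0 <- rise_ms / log(19)
  ifelse(t_from_latency < 0, 0, 2 / (1 + exp(-t_from_latency / s0)) - 1)
}

#' Simulate one pursuit trial trace
#'
#' Realises a 1-kHz horizontal/vertical eye-position trace: zero velocity
#' before `latency_ms`, then a smooth half-logistic rise toward
#' `gain * target_speed` along `theta_trial`; position is the running
#' integral of velocity. White velocity noise and an optional 30-ms,
#' 200 deg/s saccadic velocity pulse can be added. The trace is a
#' deterministic function of its inputs and the RNG state.
#'
#' @param theta_trial Pursued direction, degrees.
#' @param latency_ms Pursuit latency from motion onset, ms; must be within
#'   (50, 400).
#' @param gain Speed gain (asymptotic eye speed / target speed).
#' @param config A [task_config()].
#' @param inject_saccade_at Optional saccade onset, ms from motion onset.
#' @param vel_noise_sd White velocity noise SD per component, deg/s.
#' @param rise_ms Onset rise time (time to 90% of asymptote), ms.
#' @param theta_fun Optional function of time (ms from motion onset)
#'   returning the instantaneous pursued direction, degrees; overrides the
#'   constant `theta_trial` direction.
#' @return A tibble with columns `time_ms`, `eye_h_deg`, `eye_v_deg`.
#' @export
simulate_trial <- function(theta_trial, latency_ms, gain, config = task_config(),
                           inject_saccade_at = NULL, vel_noise_sd = 0,
                           rise_ms = 60, theta_fun = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (latency_ms <= 50 || latency_ms >= 400)
    stop("latency_ms must be within (50, 400) ms")
  fs <- config$sample_rate_hz
  dt_ms <- 1000 / fs
  time_ms <- seq(-config$pre_onset_ms, config$motion_duration_ms, by = dt_ms)
  speed <- gain * config$target_speed * onset_profile(time_ms - latency_ms, rise_ms)
  theta <- if (is.null(theta_fun)) theta_trial else theta_fun(time_ms)
  th <- deg2rad(theta)
  vh <- speed * cos(th)
  vv <- speed * sin(th)
  if (!is.null(inject_saccade_at)) {
    dur <- 30
    in_pulse <- time_ms >= inject_saccade_at & time_ms <= inject_saccade_at + dur
    pulse <- 200 * 0.5 * (1 - cos(2 * pi * (time_ms[in_pulse] - inject_saccade_at) / dur))
    dir_s <- deg2rad(if (is.null(theta_fun)) theta_trial else theta_fun(inject_saccade_at))
    vh[in_pulse] <- vh[in_pulse] + pulse * cos(dir_s)
    vv[in_pulse] <- vv[in_pulse] + pulse * sin(dir_s)
  }
  if (vel_noise_sd > 0) {
    vh <- vh + rnorm(length(time_ms), 0, vel_noise_sd)
    vv <- vv + rnorm(length(time_ms), 0, vel_noise_sd)
  }
  tibble::new_tibble(list(
    time_ms = time_ms,
    eye_h_deg = cumsum(vh) / fs,
    eye_v_deg = cumsum(vv) / fs
  ), nrow = length(time_ms))
}

# instantaneous pursued direction under a decaying likelihood SD:
# sigma_m(t) = sigma_m * (1 + A exp(-t/tau)); the MAP weight grows with t so
# the direction relaxes from a prior-dominated early estimate to the final MAP
make_theta_fun <- function(theta_s, theta_p, z, sigma_m_eff, sigma_p,
                           timecourse, motor_shift) {
  A <- timecourse[1]; tau <- timecourse[2]
  function(t) {
    sm <- sigma_m_eff * (1 + A * exp(-pmax(t, 0) / tau))
    w <- sigma_p^2 / (sigma_p^2 + sm^2)
    w * (theta_s + z * sm) + (1 - w) * theta_p + motor_shift
  }
}

#' Simulate a full two-block pursuit session
#'
#' Generates a complete session of the direction-prior task: `n_block_reps`
#' alternating narrow- and wide-prior blocks, per-direction trial counts set
#' by the block design (prior direction shown `prior_dir_weight` times as
#' often in the narrow block), high/low contrast randomly interleaved in
#' equal proportion, trial order randomised within block. Each trial's
#' pursued direction is drawn from the generative Bayesian observer
#' ([sample_trial_direction()]) with the block's prior SD and the
#' contrast-dependent likelihood SD; optional single-trial adaptation shifts
#' it by `adaptation_shift` degrees toward the previous trial's target
#' direction when the two differ (previous trial of the same block segment).
#'
#' One master seed spawns an independent per-trial stream, so any single
#' trial is reproducible regardless of how the session is reordered or
#' subset.
#'
#' @param config A [task_config()].
#' @param params A [gen_params()].
#' @param seed Integer master seed.
#' @param traces If `FALSE`, skip trace synthesis and return only the
#'   trial-level draws (`theta_trial`, latency, gain); the draws are
#'   identical to those of a `traces = TRUE` run with the same seed.
#' @return A tibble with one row per trial: `trial_index`, `block`,
#'   `block_rep`, `contrast`, `theta_s`, `theta_trial`, `latency_ms`, `gain`,
#'   `saccade_ms` (NA if none), `trial_seed`, and a `trace` list-column of
#'   position tibbles (see [simulate_trial()]).
#' @export
simulate_session <- function(config = task_config(), params = gen_params(),
                             seed = 1L, traces = TRUE) {
  stopifnot(inherits(config, "task_config"), inherits(params, "gen_params"))
  dirs <- sort(unique(c(config$narrow_directions, config$wide_directions)))
  sigma_m <- setNames(rep_len(params$sigma_m_base, length(dirs)), dirs)

  meta <- withr::with_seed(seed, {
    blocks <- purrr::map_dfr(seq_len(config$n_block_reps), function(rep_i) {
      purrr::map_dfr(c("narrow", "wide"), function(blk) {
        counts <- block_direction_counts(config, blk)
        df <- tidyr::uncount(counts, .data$n)
        df$contrast <- unlist(lapply(counts$n, function(k)
          sample(rep_len(c("high", "low"), k))))
        df <- df[sample(nrow(df)), ]
        df$block <- blk
        df$block_rep <- rep_i
        df
      })
    })
    blocks$trial_index <- seq_len(nrow(blocks))
    blocks$trial_seed <- sample.int(.Machine$integer.max, nrow(blocks))
    blocks
  })

  prev_theta_s <- c(NA, meta$theta_s[-nrow(meta)])
  same_segment <- c(FALSE, meta$block[-1] == meta$block[-nrow(meta)] &
                      meta$block_rep[-1] == meta$block_rep[-nrow(meta)])

  rows <- purrr::pmap(
    list(meta$theta_s, meta$block, meta$contrast, meta$trial_seed,
         prev_theta_s, same_segment),
    function(theta_s, block, contrast, trial_seed, prev_dir, same_seg) {
      theta_p <- config$prior_direction
      sigma_p <- if (block == "narrow") params$sigma_p_narrow else params$sigma_p_wide
      sm <- unname(sigma_m[as.character(theta_s)]) *
        if (contrast == "low") params$contrast_factor else 1
      lat_mean <- if (contrast == "low") params$latency_mean_low else params$latency_mean_high
      withr::with_seed(trial_seed, {
        z <- rnorm(1)
        motor <- if (params$motor_noise_sd > 0) rnorm(1, 0, params$motor_noise_sd) else 0
        w <- sigma_p^2 / (sigma_p^2 + sm^2)
        theta_trial <- w * (theta_s + z * sm) + (1 - w) * theta_p + motor
        latency <- min(max(rnorm(1, lat_mean, params$latency_sd), 51), 399)
        gain <- max(rnorm(1, params$gain_mean, params$gain_sd), 0.1)
        sacc <- if (runif(1) < params$saccade_prob) runif(1, 0, 370) else NA_real_
        if (!is.na(prev_dir) && same_seg &&
            abs(wrap_angle(prev_dir - theta_s)) > 1e-9) {
          theta_trial <- theta_trial +
            params$adaptation_shift * sign(wrap_angle(prev_dir - theta_s))
        }
        theta_fun <- NULL
        if (!is.null(params$sigma_m_timecourse)) {
          theta_fun <- make_theta_fun(theta_s, theta_p, z, sm,
                                      sigma_p, params$sigma_m_timecourse, motor)
          if (!is.na(prev_dir) && same_seg &&
              abs(wrap_angle(prev_dir - theta_s)) > 1e-9) {
            shift <- params$adaptation_shift * sign(wrap_angle(prev_dir - theta_s))
            base_fun <- theta_fun
            theta_fun <- function(t) base_fun(t) + shift
          }
        }
        trace <- if (!traces) NULL else
          simulate_trial(theta_trial, latency, gain, config,
                                inject_saccade_at = if (is.na(sacc)) NULL else sacc,
                                vel_noise_sd = params$vel_noise_sd,
                                rise_ms = params$rise_ms,
                                theta_fun = theta_fun)
        list(theta_trial = theta_trial, latency_ms = latency, gain = gain,
             saccade_ms = sacc, trace = trace)
      })
    }
  )

  out <- tibble::tibble(
    trial_index = meta$trial_index,
    block = meta$block,
    block_rep = meta$block_rep,
    contrast = meta$contrast,
    theta_s = meta$theta_s,
    theta_trial = purrr::map_dbl(rows, "theta_trial"),
    latency_ms = purrr::map_dbl(rows, "latency_ms"),
    gain = purrr::map_dbl(rows, "gain"),
    saccade_ms = purrr::map_dbl(rows, "saccade_ms"),
    trial_seed = meta$trial_seed,
    trace = purrr::map(rows, "trace")
  )
  attr(out, "task_config") <- config
  attr(out, "gen_params") <- params
  attr(out, "seed") <- seed
  out
}
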