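# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# small but decomposable session: enough trials per condition cell
small_config <- function(...) {
  task_config(n_trials_narrow = 120, n_trials_wide = 120, n_block_reps = 1,
              ...)
}

quiet_params <- function(...) {
  gen_params(saccade_prob = 0, ...)
}

# assemble a session tibble by hand from simulate_trial() calls
manual_session <- function(traces, theta_s, block = "narrow",
                           contrast = "high", config = task_config()) {
  n <- length(traces)
  out <- tibble::tibble(
    trial_index = seq_len(n),
    block = rep_len(block, n),
    block_rep = 1L,
    contrast = rep_len(contrast, n),
    theta_s = rep_len(theta_s, n),
    trace = traces
  )
  attr(out, "task_config") <- config
  out
}

# true MAP-moment predictions used as generative oracles in several tests
map_moments <- function(theta_s, theta_p, sigma_m, sigma_p) {
  w <- sigma_p^2 / (sigma_p^2 + sigma_m^2)
  list(mean = w * theta_s + (1 - w) * theta_p, sd = w * sigma_m, w = w)
}

# noise-free 24-point condition summaries from known observer parameters
true_summaries <- function(sigma_m, contrast_factor, sigma_p_narrow,
                           sigma_p_wide = 1e6, prior_direction = 0) {
  des <- observer_design(prior_direction)
  dirs <- sort(unique(des$theta_s))
  params <- list(
    sigma_m = stats::setNames(rep_len(sigma_m, 5), as.character(dirs)),
    contrast_factor = contrast_factor,
    sigma_p_narrow = sigma_p_narrow,
    sigma_p_wide = sigma_p_wide,
    theta_p = prior_direction
  )
  pr <- predict_design(params, des)
  dplyr::mutate(des, mean_direction_deg = pr$pred_mean,
                sd_direction_deg = pr$pred_sd)
}

# independent oracle for the MAP estimate: two-stage argmax of the Gaussian
# posterior log-density on a grid refined to 1e-4 degrees
grid_map_oracle <- function(theta_m, theta_p, sigma_m, sigma_p) {
  logpost <- function(th)
    -(th - theta_m)^2 / (2 * sigma_m^2) - (th - theta_p)^2 / (2 * sigma_p^2)
  lo <- min(theta_m, theta_p) - 1
  hi <- max(theta_m, theta_p) + 1
  coarse <- seq(lo, hi, by = 0.01)
  c0 <- coarse[which.max(logpost(coarse))]
  fine <- seq(c0 - 0.02, c0 + 0.02, by = 1e-4)
  fine[which.max(logpost(fine))]
}

# simulated per-session timecourse curves for permutation-test calibration:
# smooth within-session noise (boxcar-filtered white noise) around a flat
# baseline, mimicking the smoothed SD curves the test consumes
simulate_null_curves <- function(n_sessions, n_time = 251, sd = 1,
                                 smooth = 10) {
  t(vapply(seq_len(n_sessions), function(i) {
    x <- rnorm(n_time + smooth, 0, sd)
    as.numeric(stats::filter(x, rep(1 / smooth, smooth), sides = 2))[
      (smooth %/% 2 + 1):(smooth %/% 2 + n_time)]
  }, numeric(n_time)))
}
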