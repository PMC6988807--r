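# Template construction and single-trial direction/gain/latency recovery.

make_velocities <- function(n, theta = 30, latency = 120, gain = 1,
                            noise = 0, seed = 1, cfg = task_config()) {
  withr::with_seed(seed, purrr::map(seq_len(n), function(i) {
    differentiate(filter_positions(
      simulate_trial(theta, latency, gain, cfg, vel_noise_sd = noise)))
  }))
}

test_that("condition latency is recovered from the average speed rise", {
  vels <- make_velocities(12, latency = 120)
  expect_lt(abs(estimate_session_latency(vels) - 120), 5)
  # averaging identical trials is a no-op: same estimate as a single trial
  expect_equal(estimate_session_latency(vels[1]),
               estimate_session_latency(vels), tolerance = 1e-9)
  vels160 <- make_velocities(12, latency = 160)
  d <- estimate_session_latency(vels160) - estimate_session_latency(vels)
  expect_lt(abs(d - 40), 5)
})

test_that("a flat condition is flagged unusable", {
  t <- -300:600
  flat <- list(tibble::tibble(time_ms = t, vel_h_deg_s = 0, vel_v_deg_s = 0,
                              speed_deg_s = 0))
  expect_error(estimate_session_latency(flat), "never rises")
})

test_that("templates are rotated to exactly 45 degrees", {
  vels <- make_velocities(12, theta = 70)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  mean_dir <- atan2(mean(tmpl$template_v), mean(tmpl$template_h)) * 180 / pi
  expect_equal(mean_dir, 45, tolerance = 1e-6)
  expect_lt(abs(tmpl$rotation_deg - (45 - 70)), 2)
  expect_error(build_template(vels[1:5], lat), "at least 10")
})

test_that("a gain-1 template approaches the target speed at window end", {
  cfg <- task_config()
  vels <- make_velocities(40, theta = 45, latency = 120, gain = 1, cfg = cfg)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  end_speed <- sqrt(tail(tmpl$template_h, 1)^2 + tail(tmpl$template_v, 1)^2)
  # at latency + 100 ms the half-logistic onset has reached ~97% of 15 deg/s
  expect_gt(end_speed, 0.9 * cfg$target_speed)
  expect_lt(end_speed, 1.05 * cfg$target_speed)
})

test_that("self-fit returns identity parameters", {
  vels <- make_velocities(12, theta = 30)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  fit <- fit_trial(vels[[1]], tmpl)
  # sub-ms parabolic refinement keeps identity within interpolation error
  expect_lt(abs(fit$tau_ms), 0.05)
  expect_equal(fit$gain_h, 1, tolerance = 1e-3)
  expect_equal(fit$gain_v, 1, tolerance = 1e-3)
  expect_gt(fit$variance_explained, 1 - 1e-4)
  expect_lt(abs(wrap_angle(fit$direction_deg - 30)), 0.01)
})

test_that("known shift and scales are recovered from a transformed template", {
  vels <- make_velocities(12, theta = 30)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  # synthesise a trial that is exactly the template shifted +10 ms and
  # scaled (1.2, 0.8) in the rotated frame, then un-rotate it
  t <- vels[[1]]$time_ms
  th <- tv <- numeric(length(t))
  idx <- match(round(tmpl$time_ms + 10), t)
  th[idx] <- 1.2 * tmpl$template_h
  tv[idx] <- 0.8 * tmpl$template_v
  rot <- -tmpl$rotation_deg * pi / 180
  trial <- tibble::tibble(
    time_ms = t,
    vel_h_deg_s = cos(rot) * th - sin(rot) * tv,
    vel_v_deg_s = sin(rot) * th + cos(rot) * tv,
    speed_deg_s = sqrt(th^2 + tv^2)
  )
  fit <- fit_trial(trial, tmpl)
  expect_equal(fit$tau_ms, 10, tolerance = 0.1)
  expect_equal(fit$gain_h, 1.2, tolerance = 0.01)
  expect_equal(fit$gain_v, 0.8, tolerance = 0.0125)
  # direction offset in the rotated frame: atan2(0.8, 1.2) - 45 = -11.31 deg
  offset <- wrap_angle(fit$direction_deg - 30)
  expect_equal(offset, atan2(0.8, 1.2) * 180 / pi - 45, tolerance = 0.05)
})

test_that("a noise-only trial fails the variance-explained criterion", {
  vels <- make_velocities(12, theta = 30)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  t <- vels[[1]]$time_ms
  noise <- withr::with_seed(9, tibble::tibble(
    time_ms = t,
    vel_h_deg_s = rnorm(length(t), 0, 5),
    vel_v_deg_s = rnorm(length(t), 0, 5)
  ))
  noise$speed_deg_s <- sqrt(noise$vel_h_deg_s^2 + noise$vel_v_deg_s^2)
  fit <- fit_trial(noise, tmpl)
  expect_lt(fit$variance_explained, 0.70)
  expect_false(fit$included)
})

test_that("shift/scale recovery stays accurate under velocity noise", {
  # known (tau, a, b) per trial at 1 deg/s white velocity noise
  vels <- make_velocities(15, theta = 30)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  t <- vels[[1]]$time_ms
  rot <- -tmpl$rotation_deg * pi / 180
  n <- 100
  withr::local_seed(33)
  truth <- tibble::tibble(tau = runif(n, -20, 20),
                          a = runif(n, 0.7, 1.3), b = runif(n, 0.7, 1.3))
  errs <- purrr::pmap_dfr(truth, function(tau, a, b) {
    th <- tv <- numeric(length(t))
    idx <- match(round(tmpl$time_ms + round(tau)), t)
    th[idx] <- a * tmpl$template_h
    tv[idx] <- b * tmpl$template_v
    vh <- cos(rot) * th - sin(rot) * tv + rnorm(length(t), 0, 1)
    vv <- sin(rot) * th + cos(rot) * tv + rnorm(length(t), 0, 1)
    trial <- tibble::tibble(time_ms = t, vel_h_deg_s = vh, vel_v_deg_s = vv,
                            speed_deg_s = sqrt(vh^2 + vv^2))
    fit <- fit_trial(trial, tmpl)
    tibble::tibble(e_tau = abs(fit$tau_ms - round(tau)),
                   e_a = abs(fit$gain_h - a), e_b = abs(fit$gain_v - b))
  })
  expect_lt(median(errs$e_tau), 1)
  expect_lt(median(errs$e_a), 0.02)
  expect_lt(median(errs$e_b), 0.02)
})

test_that("variance explained decreases monotonically with noise", {
  vels <- make_velocities(12, theta = 30)
  lat <- estimate_session_latency(vels)
  tmpl <- build_template(vels, lat)
  t <- vels[[1]]$time_ms
  rot <- -tmpl$rotation_deg * pi / 180
  ve <- purrr::map_dbl(c(0.5, 2, 5, 10), function(ns) {
    withr::with_seed(44, {
      th <- tv <- numeric(length(t))
      idx <- match(round(tmpl$time_ms), t)
      th[idx] <- tmpl$template_h
      tv[idx] <- tmpl$template_v
      vh <- cos(rot) * th - sin(rot) * tv + rnorm(length(t), 0, ns)
      vv <- sin(rot) * th + cos(rot) * tv + rnorm(length(t), 0, ns)
      trial <- tibble::tibble(time_ms = t, vel_h_deg_s = vh,
                              vel_v_deg_s = vv,
                              speed_deg_s = sqrt(vh^2 + vv^2))
      fit_trial(trial, tmpl)$variance_explained
    })
  })
  expect_true(all(diff(ve) < 0))
})

test_that("direction estimates are unbiased at the condition direction", {
  cfg <- small_config()
  p <- quiet_params(sigma_m_base = 6, sigma_p_narrow = 1e5)
  sess <- simulate_session(cfg, p, seed = 55)
  kin <- decompose_session(preprocess_session(sess))
  sub <- kin[kin$included & kin$theta_s == 0 & kin$block == "narrow", ]
  truth <- sess$theta_trial[match(sub$trial_index, sess$trial_index)]
  expect_gt(nrow(sub), 40)
  expect_lt(abs(mean(sub$direction_deg - truth)), 0.5)
})

test_that("the session rule requires more than 70 prior trials per block", {
  mk_kin <- function(n_narrow, n_wide) {
    tibble::tibble(
      trial_index = seq_len(n_narrow + n_wide),
      block = rep(c("narrow", "wide"), c(n_narrow, n_wide)),
      contrast = "high",
      theta_s = 0,
      direction_deg = rnorm(n_narrow + n_wide, 0, 5),
      included = TRUE
    )
  }
  withr::local_seed(1)
  expect_true(apply_session_inclusion(mk_kin(71, 72), 0)$retained)
  expect_false(apply_session_inclusion(mk_kin(70, 72), 0)$retained)
  expect_false(apply_session_inclusion(mk_kin(71, 70), 0)$retained)
})

test_that("MAD outliers are dropped before the session count", {
  withr::local_seed(8)
  kin <- tibble::tibble(
    trial_index = 1:80,
    block = "narrow", contrast = "high", theta_s = 0,
    direction_deg = c(rnorm(78, 0, 5), 60, -75),
    included = TRUE
  )
  res <- apply_session_inclusion(kin, 0)
  expect_true(all(res$kinematics$outlier[79:80]))
  expect_equal(res$n_prior_narrow, 78)
})
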