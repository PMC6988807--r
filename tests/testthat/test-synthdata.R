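# Generative observer draws and session assembly.

test_that("trial-direction draws obey the MAP moments in limiting cases", {
  withr::local_seed(101)
  # flat prior: estimates centred on the stimulus with the full likelihood SD
  d <- sample_trial_direction(7, 0, sigma_m_eff = 14.53, sigma_p = 1e9,
                              n = 1e5)
  expect_equal(mean(d), 7, tolerance = 0.2, ignore_attr = TRUE)
  expect_equal(sd(d), 14.53, tolerance = 0.02)
  # degenerate prior: every draw collapses onto the prior mean
  d0 <- sample_trial_direction(7, 3, sigma_m_eff = 14.53, sigma_p = 1e-9,
                               n = 100)
  expect_true(all(abs(d0 - 3) < 1e-6))
})

test_that("trial-direction draws match the closed-form mean and SD", {
  # theta_s 15, prior 0, sigma_m 14.53, sigma_p 34.5: mean 12.740, SD 12.341
  mm <- map_moments(15, 0, 14.53, 34.5)
  withr::local_seed(202)
  d <- sample_trial_direction(15, 0, 14.53, 34.5, n = 1e5)
  expect_equal(mean(d), mm$mean, tolerance = 0.15 / mm$mean)
  expect_equal(sd(d), mm$sd, tolerance = 0.1 / mm$sd)
  # frozen closed-form values
  expect_equal(mm$mean, 12.7402, tolerance = 1e-4)
  expect_equal(mm$sd, 12.3410, tolerance = 1e-4)
})

test_that("non-positive dispersion parameters are rejected", {
  expect_error(sample_trial_direction(0, 0, -1, 10), "sigma_m")
  expect_error(sample_trial_direction(0, 0, 10, 0), "sigma_p")
})

test_that("empirical SD of generated directions converges to the MAP SD", {
  withr::local_seed(303)
  grid <- expand.grid(sigma_m = c(5, 10, 20), sigma_p = c(15, 40, 1e5))
  for (i in seq_len(nrow(grid))) {
    mm <- map_moments(10, 0, grid$sigma_m[i], grid$sigma_p[i])
    d <- sample_trial_direction(10, 0, grid$sigma_m[i], grid$sigma_p[i],
                                n = 1e4)
    se_sd <- mm$sd / sqrt(2 * 1e4)
    expect_lt(abs(sd(d) - mm$sd), 3 * se_sd)
  }
})

test_that("simulated traces reach the commanded speed along the right axis", {
  cfg <- task_config()
  tr <- simulate_trial(0, 120, 1, cfg)
  v <- differentiate(tr)
  terminal <- tail(v$speed_deg_s, 5)
  expect_true(all(abs(terminal - cfg$target_speed) < 0.01 * cfg$target_speed))
  expect_true(all(v$speed_deg_s[v$time_ms < 120] == 0))
  # straight-up motion: horizontal velocity stays ~0, vertical rises
  tr90 <- simulate_trial(90, 120, 1, cfg)
  v90 <- differentiate(tr90)
  expect_true(all(abs(v90$vel_h_deg_s) < 1e-9))
  expect_true(all(v90$vel_v_deg_s[v90$time_ms > 150] > 0))
})

test_that("traces are bit-identical under a repeated seed", {
  cfg <- task_config()
  t1 <- withr::with_seed(7, simulate_trial(30, 130, 1.1, cfg, vel_noise_sd = 1))
  t2 <- withr::with_seed(7, simulate_trial(30, 130, 1.1, cfg, vel_noise_sd = 1))
  expect_identical(t1, t2)
  s1 <- simulate_session(small_config(), quiet_params(), seed = 5,
                         traces = FALSE)
  s2 <- simulate_session(small_config(), quiet_params(), seed = 5,
                         traces = FALSE)
  expect_identical(s1$theta_trial, s2$theta_trial)
})

test_that("block composition follows the task design", {
  cfg <- task_config(n_block_reps = 1)
  sess <- simulate_session(cfg, quiet_params(), seed = 11, traces = FALSE)
  narrow <- table(sess$theta_s[sess$block == "narrow"])
  expect_equal(unname(narrow[c("-15", "0", "15")]), c(63, 126, 63),
               ignore_attr = TRUE)
  wide <- table(sess$theta_s[sess$block == "wide"])
  expect_equal(unname(wide[c("-120", "0", "120")]), c(126, 126, 126),
               ignore_attr = TRUE)
  # contrasts interleaved about evenly within each block
  tab <- table(sess$block, sess$contrast)
  expect_true(all(abs(tab[, "high"] - tab[, "low"]) <= 3))
})

test_that("narrow-block direction SD is below wide-block SD by construction", {
  withr::local_seed(99)
  for (sm in c(6, 12)) {
    p <- quiet_params(sigma_m_base = sm, sigma_p_narrow = 30,
                      sigma_p_wide = 1e6)
    sess <- simulate_session(small_config(), p, seed = sample.int(1e6, 1),
                             traces = FALSE)
    common <- sess$theta_s == 0
    sd_n <- sd(sess$theta_trial[common & sess$block == "narrow"])
    sd_w <- sd(sess$theta_trial[common & sess$block == "wide"])
    expect_lt(sd_n, sd_w)
  }
})

test_that("generated bias matches the shrinkage weight in expectation", {
  # direction-difference ratio of generated data converges to
  # sigma_p^2 / (sigma_p^2 + sigma_m^2)
  withr::local_seed(42)
  w <- map_moments(15, 0, 14.53, 34.5)$w
  m_pos <- mean(sample_trial_direction(15, 0, 14.53, 34.5, n = 2e4))
  m_neg <- mean(sample_trial_direction(-15, 0, 14.53, 34.5, n = 2e4))
  expect_equal(direction_difference_ratio(c(m_neg, m_pos), c(-15, 15)), w,
               tolerance = 0.02)
})

test_that("single-trial adaptation shifts directions toward the previous target", {
  cfg <- task_config(n_trials_narrow = 252, n_trials_wide = 40,
                     n_block_reps = 4)
  p <- quiet_params(adaptation_shift = 3)
  sess <- simulate_session(cfg, p, seed = 21, traces = FALSE)
  common <- sess[sess$block == "narrow" & sess$theta_s == 0, ]
  prev <- sess$theta_s[match(common$trial_index, sess$trial_index) - 1]
  stat <- adaptation_statistic(common$theta_trial, prev, 0)
  # expectation is 2 * shift = 6
  expect_equal(stat, 6, tolerance = 0.5)
  # no-adaptation null: statistic indistinguishable from zero
  p0 <- quiet_params(adaptation_shift = 0)
  sess0 <- simulate_session(cfg, p0, seed = 22, traces = FALSE)
  common0 <- sess0[sess0$block == "narrow" & sess0$theta_s == 0, ]
  prev0 <- sess0$theta_s[match(common0$trial_index, sess0$trial_index) - 1]
  stat0 <- adaptation_statistic(common0$theta_trial, prev0, 0)
  se <- sd(common0$theta_trial) * sqrt(4 / nrow(common0))
  expect_lt(abs(stat0), 3 * se)
})

test_that("session containers round-trip through the CSV layout", {
  cfg <- task_config(n_trials_narrow = 8, n_trials_wide = 9, n_block_reps = 1)
  sess <- simulate_session(cfg, quiet_params(), seed = 2)
  dir <- withr::local_tempdir()
  write_session(sess, dir, format = "csv")
  back <- read_session(dir, format = "csv")
  expect_equal(nrow(back), nrow(sess))
  expect_equal(back$theta_trial, sess$theta_trial, tolerance = 1e-9)
  expect_equal(back$trace[[3]]$eye_h_deg, sess$trace[[3]]$eye_h_deg,
               tolerance = 1e-9)
})
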