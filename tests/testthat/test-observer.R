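# Gaussian Bayesian observer: MAP arithmetic, design predictions, and the
# eight-parameter fit.

test_that("the MAP estimate is the precision-weighted average", {
  expect_equal(map_estimate(7, 0, 14.53, 1e9), 7, tolerance = 1e-6)
  expect_equal(map_estimate(10, 0, 5, 5), 5)
  expect_equal(map_estimate(15, 0, 14.53, 34.5), 12.7402, tolerance = 1e-4)
  expect_error(map_estimate(0, 0, -1, 10), "sigma_m")
})

test_that("the MAP estimate matches a brute-force posterior argmax", {
  withr::local_seed(17)
  for (i in 1:100) {
    q <- list(theta_m = runif(1, -60, 60), theta_p = runif(1, -30, 30),
              sigma_m = runif(1, 1, 30), sigma_p = runif(1, 2, 100))
    closed <- map_estimate(q$theta_m, q$theta_p, q$sigma_m, q$sigma_p)
    grid <- grid_map_oracle(q$theta_m, q$theta_p, q$sigma_m, q$sigma_p)
    expect_lt(abs(closed - grid), 1e-4 + 1e-8)
  }
})

test_that("predicted MAP moments match Monte-Carlo simulation", {
  pred <- predict_mean_sd(15, 0, 14.53, 34.5)
  expect_equal(pred$pred_mean, 12.7402, tolerance = 1e-4)
  expect_equal(pred$pred_sd, 12.3410, tolerance = 1e-4)
  n <- 1e6
  withr::local_seed(18)
  draws <- map_estimate(rnorm(n, 15, 14.53), 0, 14.53, 34.5)
  expect_lt(abs(mean(draws) - pred$pred_mean), 3 * pred$pred_sd / sqrt(n))
  expect_lt(abs(sd(draws) - pred$pred_sd), 3 * pred$pred_sd / sqrt(2 * n))
  # limits
  flat <- predict_mean_sd(15, 0, 14.53, 1e9)
  expect_equal(flat$pred_mean, 15, tolerance = 1e-6)
  expect_equal(flat$pred_sd, 14.53, tolerance = 1e-6)
  tight <- predict_mean_sd(15, 0, 14.53, 1e-9)
  expect_equal(tight$pred_mean, 0, tolerance = 1e-6)
  expect_equal(tight$pred_sd, 0, tolerance = 1e-6)
})

test_that("the predicted SD never exceeds the likelihood SD, and bias is monotone", {
  grid <- expand.grid(sm = c(2, 8, 20, 50), sp = c(5, 20, 80, 1e4))
  pr <- predict_mean_sd(15, 0, grid$sm, grid$sp)
  expect_true(all(pr$pred_sd <= grid$sm))
  # bias grows with sigma_m (fixed sigma_p) and shrinks with sigma_p
  sm_seq <- seq(2, 40, by = 2)
  bias_sm <- abs(predict_mean_sd(15, 0, sm_seq, 30)$pred_mean - 15)
  expect_true(all(diff(bias_sm) > 0))
  sp_seq <- seq(5, 200, by = 5)
  bias_sp <- abs(predict_mean_sd(15, 0, 10, sp_seq)$pred_mean - 15)
  expect_true(all(diff(bias_sp) < 0))
})

test_that("design predictions follow the block and contrast structure", {
  summ <- true_summaries(8, 1, 30)             # contrast factor 1
  high <- summ[summ$contrast == "high", ]
  low <- summ[summ$contrast == "low", ]
  expect_equal(high$mean_direction_deg, low$mean_direction_deg)
  expect_equal(high$sd_direction_deg, low$sd_direction_deg)
  # flat wide prior: wide means equal the stimulus directions
  summ2 <- true_summaries(8, 2, 30, sigma_p_wide = 1e9)
  wide <- summ2[summ2$block == "wide", ]
  expect_equal(wide$mean_direction_deg, wide$theta_s, tolerance = 1e-6)
  # narrow low-contrast outer directions shrink by the closed-form weight
  summ3 <- true_summaries(7.94, 1.83, 34.5)
  cell <- summ3[summ3$block == "narrow" & summ3$contrast == "low" &
                  summ3$theta_s == 15, ]
  w <- map_moments(15, 0, 7.94 * 1.83, 34.5)$w
  expect_equal(cell$mean_direction_deg / 15, w, tolerance = 1e-9)
  expect_equal(round(w, 2), 0.85)
})

test_that("noise-free summaries return the generating parameters", {
  summ <- true_summaries(7.94, 1.83, 34.5)
  fit <- fit_observer(summ, theta_p = 0, seed = 1)
  g <- glance(fit)
  expect_equal(g$mean_sigma_m, 7.94, tolerance = 0.005)
  expect_equal(g$contrast_factor, 1.83, tolerance = 0.005)
  expect_equal(g$sigma_p_narrow, 34.5, tolerance = 0.005)
  expect_equal(g$r2_mean, 1, tolerance = 1e-6)
  expect_equal(g$r2_sd, 1, tolerance = 1e-6)
  expect_false(g$at_bound)
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_true(all(td$estimate[1:5] > 0))
})

test_that("no prior effect drives the narrow prior SD to the flat regime", {
  # means equal the stimulus directions and SDs ignore the block: the fitted
  # narrow prior must be effectively flat
  des <- observer_design()
  summ <- dplyr::mutate(des,
                        mean_direction_deg = .data$theta_s,
                        sd_direction_deg = ifelse(.data$contrast == "low",
                                                  14, 8))
  fit <- fit_observer(summ, theta_p = 0, seed = 2)
  expect_gt(fit$params$sigma_p_narrow, 1e3)
})

test_that("the fit is equivariant to translating all direction labels", {
  g0 <- glance(fit_observer(true_summaries(7.94, 1.83, 34.5,
                                           prior_direction = 0),
                            theta_p = 0, seed = 3))
  g30 <- glance(fit_observer(true_summaries(7.94, 1.83, 34.5,
                                            prior_direction = 30),
                             theta_p = 30, seed = 3))
  expect_equal(g30$mean_sigma_m, g0$mean_sigma_m, tolerance = 1e-4)
  expect_equal(g30$contrast_factor, g0$contrast_factor, tolerance = 1e-4)
  expect_equal(g30$sigma_p_narrow, g0$sigma_p_narrow, tolerance = 1e-4)
})

test_that("incomplete summaries are rejected", {
  summ <- true_summaries(8, 2, 30)
  expect_error(fit_observer(summ[1:10, ], theta_p = 0), "24 summary values")
  bad <- summ
  bad$sd_direction_deg[4] <- NA
  expect_error(fit_observer(bad, theta_p = 0), "24 summary values")
})
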