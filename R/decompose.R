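# Open-loop decomposition: each trial's velocity is modelled as a shifted,
# component-scaled copy of the condition template; direction, speed gain and
# latency fall out of the fitted shift and scales.

#' Estimate the average pursuit latency of a condition
#'
#' Averages speed over trials, then finds the first time (from motion onset)
#' at which the average speed exceeds `frac` (default 10%) of its value at
#' `t_ref` (default +250 ms), and refines it by fitting a line to the
#' 10-50% portion of the rise and extrapolating back to zero speed.
#'
#' @param velocities List of velocity tibbles (one condition's trials), all
#'   on the same time base.
#' @param t_ref Reference time for the plateau speed, ms.
#' @param frac Threshold fraction of the reference speed.
#' @return Latency in ms from motion onset.
#' @export
estimate_session_latency <- function(velocities, t_ref = 250, frac = 0.10) {
  stopifnot(length(velocities) >= 1)
  t <- velocities[[1]]$time_ms
  sp <- rowMeans(vapply(velocities, function(v) v$speed_deg_s,
                        numeric(length(t))))
  i_ref <- which.min(abs(t - t_ref))
  v_ref <- sp[i_ref]
  post <- t >= 0 & t <= t_ref
  cross <- which(post & sp >= frac * v_ref)
  if (length(cross) == 0 || v_ref <= 0)
    stop("average speed never rises above threshold; condition unusable")
  i10 <- cross[1]
  rise <- i10:i_ref
  rise <- rise[sp[rise] <= 0.5 * v_ref]
  if (length(rise) < 3) rise <- i10:min(i10 + 10, length(t))
  fit <- lm(sp[rise] ~ t[rise])
  lat <- -coef(fit)[1] / coef(fit)[2]
  unname(lat)
}

#' Build a pursuit template for one condition
#'
#' Averages the horizontal and vertical velocity components over the window
#' from -20 to +100 ms around the condition's average pursuit latency, and
#' rotates the average so that its mean direction is exactly 45 degrees.
#' Individual trials are rotated by the same angle before template fitting,
#' which makes the single-trial direction estimate unbiased at the condition
#' direction.
#'
#' @param velocities List of velocity tibbles (the condition's trials).
#' @param latency_ms Condition latency from [estimate_session_latency()].
#' @param window Template window relative to `latency_ms`, ms.
#' @param min_trials Minimum number of trials required.
#' @return Object of class `"pursuit_template"`: window times, rotated
#'   template components, rotation angle, latency and trial count.
#' @export
build_template <- function(velocities, latency_ms, window = c(-20, 100),
                           min_trials = 10) {
  if (length(velocities) < min_trials)
    stop("need at least ", min_trials, " trials to build a template")
  t <- velocities[[1]]$time_ms
  mask <- t >= round(latency_ms + window[1]) & t <= round(latency_ms + window[2])
  th <- rowMeans(vapply(velocities, function(v) v$vel_h_deg_s[mask],
                        numeric(sum(mask))))
  tv <- rowMeans(vapply(velocities, function(v) v$vel_v_deg_s[mask],
                        numeric(sum(mask))))
  mean_dir <- atan2_deg(mean(tv), mean(th))
  rot <- 45 - mean_dir
  cr <- cos(deg2rad(rot)); sr <- sin(deg2rad(rot))
  structure(list(
    time_ms = t[mask],
    template_h = cr * th - sr * tv,
    template_v = sr * th + cr * tv,
    rotation_deg = rot,
    mean_direction_deg = mean_dir,
    latency_ms = latency_ms,
    window = window,
    n_trials = length(velocities)
  ), class = "pursuit_template")
}

#' Fit the condition template to one trial
#'
#' Slides the two template components jointly over the trial (shift tau in
#' `+/- max_shift_ms`) and scales them independently, minimising
#' `sum[(e_h - a T_h(t - tau))^2 + (e_v - b T_v(t - tau))^2]`. For fixed tau
#' the scales have closed-form least-squares solutions; tau is found by 1-ms
#' grid search followed by parabolic refinement. The trial's pursuit
#' direction is `atan2(b, a)` rotated back from the template's 45-degree
#' frame to the stimulus frame; gain is `(a + b) / 2`; variance explained is
#' `1 - SSE/SST` over the fit window.
#'
#' @param velocity Velocity tibble of one trial.
#' @param template A [build_template()] result.
#' @param max_shift_ms Half-width of the shift search, ms.
#' @return One-row tibble: `tau_ms`, `latency_ms`, `gain_h`, `gain_v`,
#'   `gain`, `direction_deg`, `variance_explained`, `included`,
#'   `tau_at_bound`.
#' @export
fit_trial <- function(velocity, template, max_shift_ms = 50) {
  fit_trials(list(velocity), template, max_shift_ms)
}

# shared workhorse: fits the template to each trial of one condition,
# reusing the sliding-window index matrix across trials
fit_trials <- function(velocities, template, max_shift_ms = 50,
                       ve_thresh = 0.70) {
  Th <- template$template_h
  Tv <- template$template_v
  ssTh <- sum(Th^2); ssTv <- sum(Tv^2)
  if (ssTh + ssTv < 1e-12) stop("degenerate (all-zero) template")
  cr <- cos(deg2rad(template$rotation_deg))
  sr <- sin(deg2rad(template$rotation_deg))
  t <- velocities[[1]]$time_ms
  dt <- t[2] - t[1]
  idx0 <- match(round(template$time_ms), round(t))
  if (anyNA(idx0)) stop("template window outside trial time base")
  taus <- seq(-max_shift_ms, max_shift_ms, by = dt)
  IDX <- outer(round(taus / dt), idx0, "+")
  ok <- IDX >= 1 & IDX <= length(t)
  any_edge <- !all(ok)
  IDX[!ok] <- 1L
  n <- length(velocities)
  tau_v <- a_v <- b_v <- ve_v <- numeric(n)
  bound_v <- logical(n)
  for (i in seq_len(n)) {
    vel <- velocities[[i]]
    eh <- cr * vel$vel_h_deg_s - sr * vel$vel_v_deg_s
    ev <- sr * vel$vel_h_deg_s + cr * vel$vel_v_deg_s
    Eh <- matrix(eh[IDX], nrow(IDX))
    Ev <- matrix(ev[IDX], nrow(IDX))
    if (any_edge) { Eh[!ok] <- 0; Ev[!ok] <- 0 }
    a_all <- as.numeric(Eh %*% Th) / ssTh
    b_all <- as.numeric(Ev %*% Tv) / ssTv
    sse <- rowSums(Eh^2) + rowSums(Ev^2) - a_all^2 * ssTh - b_all^2 * ssTv
    i_best <- which.min(sse)
    tau <- taus[i_best]
    at_bound <- i_best == 1 || i_best == length(taus)
    if (!at_bound) {
      s0 <- sse[i_best]; sm <- sse[i_best - 1]; sp <- sse[i_best + 1]
      denom <- sm - 2 * s0 + sp
      if (denom > 0) tau <- tau + dt * 0.5 * (sm - sp) / denom
    }
    # recompute scales at the refined (fractional-ms) shift
    w_t <- template$time_ms + tau
    ehw <- approx(t, eh, xout = w_t, rule = 2)$y
    evw <- approx(t, ev, xout = w_t, rule = 2)$y
    a <- sum(ehw * Th) / ssTh
    b <- sum(evw * Tv) / ssTv
    sse_f <- sum((ehw - a * Th)^2) + sum((evw - b * Tv)^2)
    sst <- sum((ehw - mean(ehw))^2) + sum((evw - mean(evw))^2)
    tau_v[i] <- tau; a_v[i] <- a; b_v[i] <- b; bound_v[i] <- at_bound
    ve_v[i] <- if (sst > 0) max(0, min(1, 1 - sse_f / sst)) else 0
  }
  tibble::new_tibble(list(
    tau_ms = tau_v,
    latency_ms = template$latency_ms + tau_v,
    gain_h = a_v, gain_v = b_v, gain = (a_v + b_v) / 2,
    direction_deg = atan2_deg(b_v, a_v) - template$rotation_deg,
    variance_explained = ve_v,
    included = ve_v > ve_thresh,
    tau_at_bound = bound_v
  ), nrow = n)
}

#' Decompose every trial of a session into direction, gain and latency
#'
#' Groups trials by condition (direction x contrast x block), estimates the
#' condition latency, builds the condition template, and fits it to each
#' trial. Trials whose fit explains 70% or less of the data variance are
#' marked not included.
#'
#' @param session Preprocessed, saccade-excluded session tibble (must carry a
#'   `velocity` list-column; see [preprocess_session()] and
#'   [exclude_trials()]).
#' @param window Template window relative to the condition latency, ms.
#' @param max_shift_ms Shift search half-width, ms.
#' @param min_trials Minimum trials per condition; smaller conditions are
#'   returned unfitted (`included = FALSE`).
#' @param ve_thresh Variance-explained inclusion threshold.
#' @return Per-trial kinematics tibble: session metadata columns plus
#'   `direction_deg`, `gain_h`, `gain_v`, `gain`, `latency_ms`, `tau_ms`,
#'   `variance_explained`, `included`, `tau_at_bound`.
#' @export
decompose_session <- function(session, window = c(-20, 100),
                              max_shift_ms = 50, min_trials = 10,
                              ve_thresh = 0.70) {
  stopifnot("velocity" %in% names(session))
  meta <- dplyr::select(session, "trial_index", "block", "contrast", "theta_s")
  groups <- dplyr::group_split(
    dplyr::group_by(tibble::tibble(meta, velocity = session$velocity),
                    .data$block, .data$contrast, .data$theta_s))
  out <- purrr::map_dfr(groups, function(g) {
    base <- dplyr::select(g, "trial_index", "block", "contrast", "theta_s")
    if (nrow(g) < min_trials) {
      return(dplyr::mutate(base, direction_deg = NA_real_, gain_h = NA_real_,
                           gain_v = NA_real_, gain = NA_real_,
                           latency_ms = NA_real_, tau_ms = NA_real_,
                           variance_explained = NA_real_, included = FALSE,
                           tau_at_bound = NA))
    }
    lat <- estimate_session_latency(g$velocity)
    tmpl <- build_template(g$velocity, lat, window = window,
                           min_trials = min_trials)
    fits <- fit_trials(g$velocity, tmpl, max_shift_ms = max_shift_ms,
                       ve_thresh = ve_thresh)
    fits$direction_deg <- unwrap_to(fits$direction_deg, g$theta_s[1])
    dplyr::bind_cols(base, fits)
  })
  out <- dplyr::arrange(out, .data$trial_index)
  attr(out, "task_config") <- attr(session, "task_config")
  out
}

#' Apply per-trial outlier removal and the session-level inclusion rule
#'
#' Within each condition, trials whose direction lies more than
#' `mad_k` median absolute deviations from the condition median are dropped
#' (marked not included). The session is then retained only if strictly more
#' than `min_prior_trials` included prior-direction trials remain in each
#' block type.
#'
#' @param kinematics Tibble from [decompose_session()].
#' @param prior_direction Prior (common) direction, degrees.
#' @param min_prior_trials Strict lower bound on included prior-direction
#'   trials per block.
#' @param mad_k Outlier cut in MAD units.
#' @return List: `kinematics` (updated `included` plus `outlier` flag),
#'   `retained` (logical), `n_prior_narrow`, `n_prior_wide`.
#' @export
apply_session_inclusion <- function(kinematics, prior_direction,
                                    min_prior_trials = 70, mad_k = 3) {
  kin <- dplyr::group_by(kinematics, .data$block, .data$contrast, .data$theta_s)
  kin <- dplyr::mutate(kin, outlier = {
    d <- unwrap_to(.data$direction_deg, .data$theta_s[1])
    med <- median(d[.data$included], na.rm = TRUE)
    s <- mad(d[.data$included], na.rm = TRUE)
    if (is.na(s) || s == 0) rep(FALSE, length(d))
    else !is.na(d) & abs(d - med) > mad_k * s
  })
  kin <- dplyr::ungroup(kin)
  kin$included <- kin$included & !kin$outlier
  is_prior <- abs(wrap_angle(kin$theta_s - prior_direction)) < 1e-9
  n_narrow <- sum(kin$included & is_prior & kin$block == "narrow")
  n_wide <- sum(kin$included & is_prior & kin$block == "wide")
  list(
    kinematics = kin,
    retained = n_narrow > min_prior_trials && n_wide > min_prior_trials,
    n_prior_narrow = n_narrow,
    n_prior_wide = n_wide
  )
}
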