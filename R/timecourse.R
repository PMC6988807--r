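# Time-resolved bias and precision over the open-loop period, and the
# cluster-based permutation comparison across prior conditions.

#' Instantaneous pursuit direction of a velocity trace
#'
#' `atan2(vel_v, vel_h)` in degrees at every sample, masked (`NA`) wherever
#' the radial speed is below `speed_floor` (direction of a near-zero
#' velocity vector is noise).
#'
#' @param velocity Velocity tibble from [differentiate()].
#' @param speed_floor Minimum speed for a defined direction, deg/s.
#' @return Numeric vector of directions (degrees) aligned with
#'   `velocity$time_ms`, `NA` below the floor.
#' @export
instantaneous_direction <- function(velocity, speed_floor = 1) {
  d <- atan2_deg(velocity$vel_v_deg_s, velocity$vel_h_deg_s)
  d[velocity$speed_deg_s < speed_floor] <- NA_real_
  d
}

# boxcar smoothing that tolerates NA gaps (gaps stay NA)
boxcar_smooth <- function(x, width) {
  if (width <= 1) return(x)
  n <- length(x)
  half <- floor(width / 2)
  out <- vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  out[is.na(x)] <- NA_real_
  out
}

#' Time-resolved bias and precision curves for one session
#'
#' At every millisecond of the open-loop period, computes per
#' (block x contrast): the direction-difference ratio from the mean
#' instantaneous directions of the two outer targets, and the SD of
#' instantaneous direction over trials of the common (prior) direction.
#' Curves are smoothed with a short boxcar and masked where fewer than
#' `min_n` trials have a defined direction.
#'
#' @param session Preprocessed (and saccade-excluded) session tibble with a
#'   `velocity` list-column.
#' @param config The session's [task_config()]; defaults to the session
#'   attribute.
#' @param t_range Analysis window, ms from motion onset.
#' @param speed_floor Minimum speed for a defined direction, deg/s.
#' @param boxcar_ms Boxcar smoothing width, ms.
#' @param min_n Minimum trials per time point.
#' @return Tibble: `time_ms`, `block`, `contrast`, `bias_ratio`, `sd_deg`,
#'   `n_common`.
#' @export
session_timecourse <- function(session, config = NULL, t_range = c(0, 250),
                               speed_floor = 1, boxcar_ms = 10, min_n = 5) {
  config <- config %||% attr(session, "task_config")
  if (is.null(config)) stop("pass the task_config")
  prior <- config$prior_direction
  t_all <- session$velocity[[1]]$time_ms
  mask <- t_all >= t_range[1] & t_all <= t_range[2]
  t_out <- t_all[mask]

  dir_mat <- vapply(seq_len(nrow(session)), function(i) {
    d <- instantaneous_direction(session$velocity[[i]], speed_floor)[mask]
    unwrap_to(d, session$theta_s[i])
  }, numeric(sum(mask)))

  purrr::map_dfr(
    tidyr::expand_grid(block = c("narrow", "wide"),
                       contrast = c("high", "low")) |> purrr::transpose(),
    function(cell) {
      dirs <- if (cell$block == "narrow") config$narrow_directions else
        config$wide_directions
      outer <- sort(setdiff(dirs, prior))
      sel <- session$block == cell$block & session$contrast == cell$contrast
      mean_dir <- function(target) {
        cols <- which(sel & abs(wrap_angle(session$theta_s - target)) < 1e-9)
        if (length(cols) == 0) return(rep(NA_real_, length(t_out)))
        m <- dir_mat[, cols, drop = FALSE]
        n_ok <- rowSums(!is.na(m))
        out <- rowMeans(m, na.rm = TRUE)
        out[n_ok < min_n] <- NA_real_
        out
      }
      m1 <- mean_dir(outer[1]); m2 <- mean_dir(outer[2])
      sep <- abs(outer[2] - outer[1])
      bias <- abs(unwrap_to(m2, outer[2]) - unwrap_to(m1, outer[1])) / sep
      cols <- which(sel & abs(wrap_angle(session$theta_s - prior)) < 1e-9)
      m <- dir_mat[, cols, drop = FALSE]
      n_ok <- rowSums(!is.na(m))
      sdv <- apply(m, 1, sd, na.rm = TRUE)
      sdv[n_ok < min_n] <- NA_real_
      tibble::tibble(
        time_ms = t_out, block = cell$block, contrast = cell$contrast,
        bias_ratio = boxcar_smooth(bias, boxcar_ms),
        sd_deg = boxcar_smooth(sdv, boxcar_ms),
        n_common = n_ok
      )
    })
}

#' Average timecourse statistics across sessions
#'
#' @param timecourses List of [session_timecourse()] tibbles (>= 5 sessions).
#' @return Tibble: `time_ms`, `block`, `contrast`, `bias_ratio`, `sd_deg`
#'   (across-session means), `se_bias`, `se_sd`, `n_sessions`.
#' @export
timecourse_statistics <- function(timecourses) {
  if (length(timecourses) < 5) stop("need at least 5 sessions")
  all_tc <- dplyr::bind_rows(timecourses, .id = "session")
  dplyr::summarise(
    dplyr::group_by(all_tc, .data$time_ms, .data$block, .data$contrast),
    se_bias = sd(.data$bias_ratio, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$bias_ratio))),
    se_sd = sd(.data$sd_deg, na.rm = TRUE) / sqrt(sum(!is.na(.data$sd_deg))),
    bias_ratio = mean(.data$bias_ratio, na.rm = TRUE),
    sd_deg = mean(.data$sd_deg, na.rm = TRUE),
    n_sessions = dplyr::n(),
    .groups = "drop"
  )
}

#' Extract a sessions-by-time matrix of one timecourse statistic
#'
#' @param timecourses List of [session_timecourse()] tibbles.
#' @param stat `"bias_ratio"` or `"sd_deg"`.
#' @param block,contrast Condition selectors.
#' @return Matrix (sessions x time) with the time axis in
#'   `attr(, "time_ms")`.
#' @export
timecourse_matrix <- function(timecourses, stat = c("sd_deg", "bias_ratio"),
                              block = "narrow", contrast = "low") {
  stat <- match.arg(stat)
  rows <- purrr::map(timecourses, function(tc) {
    sub <- tc[tc$block == block & tc$contrast == contrast, ]
    sub <- sub[order(sub$time_ms), ]
    setNames(sub[[stat]], sub$time_ms)
  })
  t_ms <- as.numeric(names(rows[[1]]))
  m <- do.call(rbind, rows)
  attr(m, "time_ms") <- t_ms
  m
}

#' Cluster-based permutation test on paired session curves
#'
#' Compares two within-session curves (e.g. narrow- vs wide-prior SD
#' timecourses) with a two-sided cluster-based permutation test: per-time
#' paired t statistics are thresholded at
#' `t_crit = qt(1 - cluster_alpha/2, n - 1)`, contiguous supra-threshold
#' samples form clusters whose mass is the summed `|t|`, and the null
#' distribution of the maximum cluster mass is built by random within-session
#' sign flips of the paired differences. Cluster p-values are the fraction
#' of permutations (observed labelling included) whose maximum mass reaches
#' the cluster's mass, so p is always in (0, 1].
#'
#' @param curves_a,curves_b Sessions-by-time matrices on a common axis
#'   (e.g. from [timecourse_matrix()]).
#' @param time_ms Time axis; defaults to `attr(curves_a, "time_ms")` or
#'   column index.
#' @param n_perm Number of sign-flip permutations.
#' @param cluster_alpha Cluster-forming (per-time) alpha.
#' @param alpha Family-wise alpha used to flag significant clusters.
#' @param seed Integer seed for the sign flips.
#' @return Object of class `"cluster_result"`: tibble of clusters
#'   (`start_ms`, `end_ms`, `mass`, `p_value`, `significant`) with the
#'   per-time t curve, threshold and settings as attributes.
#' @export
cluster_permutation_test <- function(curves_a, curves_b, time_ms = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     alpha = 0.05, seed = 1L) {
  stopifnot(all(dim(curves_a) == dim(curves_b)))
  n <- nrow(curves_a)
  if (n < 5) stop("need at least 5 paired sessions")
  time_ms <- time_ms %||% attr(curves_a, "time_ms") %||% seq_len(ncol(curves_a))
  d <- curves_a - curves_b
  valid <- apply(d, 2, function(x) all(is.finite(x)))
  t_crit <- qt(1 - cluster_alpha / 2, n - 1)

  col_t <- function(m, ss) {
    mu <- colMeans(m)
    v <- pmax((ss - n * mu^2) / (n - 1), 0)
    out <- ifelse(v > 0, mu / sqrt(v / n),
                  ifelse(abs(mu) > 0, sign(mu) * Inf, 0))
    out
  }
  ss <- colSums(d^2)
  t_obs <- rep(NA_real_, ncol(d))
  t_obs[valid] <- col_t(d, ss)[valid]

  find_clusters <- function(tv) {
    above <- !is.na(tv) & abs(tv) > t_crit
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(i0 = starts[keep], i1 = ends[keep],
               mass = vapply(which(keep), function(k)
                 sum(abs(tv[starts[k]:ends[k]])), numeric(1)))
  }
  obs <- find_clusters(t_obs)

  signs <- withr::with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  M <- signs %*% d / n
  V <- pmax(sweep(-n * M^2, 2, ss, "+") / (n - 1), 0)
  Tm <- ifelse(V > 0, M / sqrt(V / n), ifelse(abs(M) > 0, sign(M) * Inf, 0))
  Tm[, !valid] <- NA_real_
  max_mass <- vapply(seq_len(n_perm), function(i) {
    cl <- find_clusters(Tm[i, ])
    if (is.null(cl)) 0 else max(cl$mass)
  }, numeric(1))

  clusters <- if (is.null(obs)) {
    tibble::tibble(start_ms = numeric(), end_ms = numeric(), mass = numeric(),
                   p_value = numeric(), significant = logical())
  } else {
    p <- vapply(obs$mass, function(m)
      (1 + sum(max_mass >= m)) / (n_perm + 1), numeric(1))
    tibble::tibble(start_ms = time_ms[obs$i0], end_ms = time_ms[obs$i1],
                   mass = obs$mass, p_value = p, significant = p < alpha)
  }
  structure(clusters, class = c("cluster_result", class(clusters)),
            time_ms = time_ms, t_stat = t_obs, t_crit = t_crit,
            n_perm = n_perm, n_sessions = n, seed = seed, alpha = alpha)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "Cluster-based permutation test (%d sessions, %d permutations, |t| > %.2f)\n",
    attr(x, "n_sessions"), attr(x, "n_perm"), attr(x, "t_crit")))
  if (nrow(x) == 0) cat("  no supra-threshold clusters\n")
  else print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Plot the timecourse t statistic and significant clusters
#'
#' @param object A [cluster_permutation_test()] result.
#' @param ... Unused.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(time_ms = attr(object, "time_ms"),
                       t = attr(object, "t_stat"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * attr(object, "t_crit"),
                        linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from motion onset (ms)", y = "paired t",
                  title = "Cluster-based permutation test") +
    ggplot2::theme_minimal()
  sig <- object[object$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    p <- p + ggplot2::annotate("rect", xmin = sig$start_ms, xmax = sig$end_ms,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}
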