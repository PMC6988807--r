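# Session-level bias and precision statistics of pursuit direction.

#' Direction-difference ratio (bias toward the central direction)
#'
#' Angular separation of the mean pursuit directions for the two outer
#' targets divided by the separation of the target directions themselves.
#' A ratio below 1 means the pursuit directions were attracted toward the
#' central (prior) direction; 1 means no attraction.
#'
#' @param pursuit_dirs Length-2 numeric: mean pursuit direction for each
#'   outer target, degrees.
#' @param target_dirs Length-2 numeric: the two outer target directions,
#'   degrees.
#' @return Dimensionless ratio (>= 0).
#' @examples
#' direction_difference_ratio(c(12, -12), c(15, -15)) # 0.8
#' @export
direction_difference_ratio <- function(pursuit_dirs, target_dirs) {
  stopifnot(length(pursuit_dirs) == 2, length(target_dirs) == 2)
  d_target <- abs(wrap_angle(target_dirs[2] - target_dirs[1]))
  if (d_target == 0) stop("outer target directions are identical")
  # unwrap each pursuit direction around its own target so the 240-degree
  # wide-block separation is measured on the same branch as the targets
  p <- unwrap_to(pursuit_dirs, target_dirs)
  d_pursuit <- abs(p[2] - p[1])
  sep <- abs(target_dirs[2] - target_dirs[1])
  d_pursuit / sep
}

#' Robust SD of pursuit directions
#'
#' Sample SD of the trial directions after unwrapping around their median
#' and removing outliers beyond `mad_k` median absolute deviations.
#'
#' @param directions Trial pursuit directions, degrees.
#' @param mad_k Outlier cut in MAD units; `Inf` disables removal.
#' @param ref Reference direction for unwrapping; defaults to the circular
#'   branch of the first direction.
#' @return SD in degrees.
#' @export
pursuit_direction_sd <- function(directions, mad_k = 3, ref = NULL) {
  directions <- directions[!is.na(directions)]
  if (length(directions) < 2) stop("need at least 2 directions")
  ref <- ref %||% directions[1]
  d <- unwrap_to(directions, ref)
  d <- unwrap_to(d, median(d))
  if (is.finite(mad_k)) {
    s <- mad(d)
    if (s > 0) d <- d[abs(d - median(d)) <= mad_k * s]
  }
  sd(d)
}

#' One-sample t-test of ratios against 1 on the log scale
#'
#' Two-sided one-sample t-test of `log(ratio)` against 0, the standard test
#' of whether a positive ratio differs from 1.
#'
#' @param ratios Per-session ratios (> 0), at least 5.
#' @return One-row tibble: `mean_ratio` (arithmetic), `geo_mean_ratio`,
#'   `t`, `df`, `p_value`, `n`.
#' @export
log_ratio_ttest <- function(ratios) {
  if (length(ratios) < 5) stop("need at least 5 sessions")
  if (any(ratios <= 0)) stop("ratios must be positive")
  lr <- log(ratios)
  if (sd(lr) == 0) {
    # degenerate all-equal input: t is 0/0 at the null, +/-Inf otherwise
    t_stat <- if (mean(lr) == 0) 0 else sign(mean(lr)) * Inf
    p <- if (mean(lr) == 0) 1 else 0
    return(tibble::tibble(mean_ratio = mean(ratios),
                          geo_mean_ratio = exp(mean(lr)), t = t_stat,
                          df = length(ratios) - 1, p_value = p,
                          n = length(ratios)))
  }
  tt <- t.test(lr, mu = 0)
  tibble::tibble(
    mean_ratio = mean(ratios),
    geo_mean_ratio = exp(mean(lr)),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n = length(ratios)
  )
}

#' Rank correlation between bias and precision ratios
#'
#' Spearman correlation between the per-session direction-difference ratio
#' ratios and SD ratios, testing whether sessions in which the prior biased
#' pursuit more were also the sessions in which it stabilised pursuit more.
#'
#' @param bias_ratios,sd_ratios Paired per-session values (n >= 10).
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
bias_precision_correlation <- function(bias_ratios, sd_ratios) {
  ok <- complete.cases(bias_ratios, sd_ratios)
  x <- bias_ratios[ok]; y <- sd_ratios[ok]
  if (length(x) < 10) stop("need at least 10 paired sessions")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: rank correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Single-trial adaptation statistic
#'
#' For trials of a common target direction whose previous trial moved in a
#' different direction: the mean pursuit direction of trials whose previous
#' target was counterclockwise of the current one, minus the mean of trials
#' whose previous target was clockwise. Positive values mean the current
#' pursuit direction is attracted toward the previous trial's direction.
#'
#' @param directions Pursuit directions of the current trials, degrees.
#' @param prev_target_dirs Target direction of each trial's previous trial,
#'   degrees.
#' @param current_target_dir Target direction of the current trials, degrees.
#' @return Difference in degrees, or `NA` (with a warning) if either subset
#'   is empty.
#' @export
adaptation_statistic <- function(directions, prev_target_dirs,
                                 current_target_dir) {
  stopifnot(length(directions) == length(prev_target_dirs))
  rel <- wrap_angle(prev_target_dirs - current_target_dir)
  differs <- !is.na(rel) & abs(rel) > 1e-9 & !is.na(directions)
  d <- unwrap_to(directions[differs], current_target_dir)
  ccw <- rel[differs] > 0
  if (!any(ccw) || !any(!ccw)) {
    warning("one of the previous-direction subsets is empty")
    return(NA_real_)
  }
  mean(d[ccw]) - mean(d[!ccw])
}

#' Per-condition summaries of decomposed trials
#'
#' Mean and robust SD of the included trials' pursuit directions for every
#' (direction x contrast x block) cell: the 12 means and 12 SDs that the
#' Bayesian observer model is fitted to.
#'
#' @param kinematics Tibble from [decompose_session()] (after
#'   [apply_session_inclusion()] if outlier removal is wanted there;
#'   otherwise `mad_k` applies it per cell here).
#' @param mad_k Outlier cut used by [pursuit_direction_sd()].
#' @return Tibble: `block`, `contrast`, `theta_s`, `n_trials`,
#'   `mean_direction_deg`, `sd_direction_deg`.
#' @export
condition_summaries <- function(kinematics, mad_k = 3) {
  kin <- dplyr::filter(kinematics, .data$included)
  dplyr::summarise(
    dplyr::group_by(kin, .data$block, .data$contrast, .data$theta_s),
    n_trials = dplyr::n(),
    mean_direction_deg = mean(unwrap_to(.data$direction_deg, .data$theta_s[1])),
    sd_direction_deg = if (dplyr::n() < 2) NA_real_ else
      pursuit_direction_sd(.data$direction_deg, mad_k = mad_k,
                           ref = .data$theta_s[1]),
    .groups = "drop"
  )
}

#' Session-level bias, precision and adaptation statistics
#'
#' Computes, for one session's decomposed trials: the direction-difference
#' ratio per (block x contrast), the narrow/wide SD ratio of the common
#' direction per contrast, and the single-trial adaptation statistic per
#' (block x contrast).
#'
#' @param kinematics Tibble from [decompose_session()].
#' @param config The session's [task_config()] (defaults to the attribute
#'   carried by `kinematics`).
#' @param mad_k Outlier cut for the SD estimate.
#' @return List of tibbles: `bias` (`block`, `contrast`, `ratio`),
#'   `sd_ratio` (`contrast`, `sd_narrow`, `sd_wide`, `ratio`),
#'   `adaptation` (`block`, `contrast`, `adaptation_deg`).
#' @export
session_statistics <- function(kinematics, config = NULL, mad_k = 3) {
  config <- config %||% attr(kinematics, "task_config")
  if (is.null(config)) stop("pass the task_config")
  prior <- config$prior_direction
  kin <- dplyr::filter(kinematics, .data$included)

  bias <- purrr::map_dfr(
    tidyr::expand_grid(block = c("narrow", "wide"),
                       contrast = c("high", "low")) |> purrr::transpose(),
    function(cell) {
      dirs <- if (cell$block == "narrow") config$narrow_directions else
        config$wide_directions
      outer <- setdiff(dirs, prior)
      sub <- dplyr::filter(kin, .data$block == cell$block,
                           .data$contrast == cell$contrast,
                           .data$theta_s %in% outer)
      mdirs <- vapply(sort(outer), function(d) {
        x <- sub$direction_deg[sub$theta_s == d]
        if (length(x) == 0) NA_real_ else mean(unwrap_to(x, d))
      }, numeric(1))
      tibble::tibble(block = cell$block, contrast = cell$contrast,
                     ratio = if (anyNA(mdirs)) NA_real_ else
                       direction_difference_ratio(mdirs, sort(outer)))
    })

  sd_ratio <- purrr::map_dfr(c("high", "low"), function(con) {
    s <- vapply(c("narrow", "wide"), function(blk) {
      x <- kin$direction_deg[kin$block == blk & kin$contrast == con &
                               abs(wrap_angle(kin$theta_s - prior)) < 1e-9]
      if (length(x) < 2) NA_real_ else
        pursuit_direction_sd(x, mad_k = mad_k, ref = prior)
    }, numeric(1))
    tibble::tibble(contrast = con, sd_narrow = s[["narrow"]],
                   sd_wide = s[["wide"]], ratio = s[["narrow"]] / s[["wide"]])
  })

  adaptation <- purrr::map_dfr(
    tidyr::expand_grid(block = c("narrow", "wide"),
                       contrast = c("high", "low")) |> purrr::transpose(),
    function(cell) {
      sub <- dplyr::filter(kinematics, .data$block == cell$block,
                           .data$contrast == cell$contrast)
      # previous trial within the session ordering of the full kinematics
      ord <- kinematics[order(kinematics$trial_index), ]
      prev <- c(NA, ord$theta_s[-nrow(ord)])
      prev_map <- setNames(prev, ord$trial_index)
      cur <- dplyr::filter(sub, .data$included,
                           abs(wrap_angle(.data$theta_s - prior)) < 1e-9)
      val <- if (nrow(cur) == 0) NA_real_ else
        suppressWarnings(adaptation_statistic(
          cur$direction_deg, unname(prev_map[as.character(cur$trial_index)]),
          prior))
      tibble::tibble(block = cell$block, contrast = cell$contrast,
                     adaptation_deg = val)
    })

  list(bias = bias, sd_ratio = sd_ratio, adaptation = adaptation)
}
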