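# End-to-end orchestration: simulate -> preprocess -> decompose -> statistics
# -> observer fit (-> timecourse), with per-stage artifacts and a manifest.

#' Analyse one session end to end
#'
#' Runs preprocessing, saccade-window exclusion, open-loop decomposition,
#' the session inclusion rule, condition summaries, session statistics and
#' (optionally) the Bayesian observer fit on one session.
#'
#' @param session Session tibble from [simulate_session()] or
#'   [read_session()].
#' @param config The session's [task_config()]; defaults to the attribute.
#' @param exclusion_window Saccade-exclusion window, ms.
#' @param fit_observer Whether to fit the observer model to the session's
#'   12 condition summaries.
#' @param fit_seed Seed for the observer fit multi-starts.
#' @param ... Passed to [preprocess_session()].
#' @return List: `kinematics`, `inclusion` (see
#'   [apply_session_inclusion()]), `summaries`, `statistics`
#'   (see [session_statistics()]), `exclusions`, `observer` (an
#'   `observer_fit` or `NULL`).
#' @export
analyze_session <- function(session, config = NULL,
                            exclusion_window = c(-100, 250),
                            fit_observer = FALSE, fit_seed = 1L, ...) {
  config <- config %||% attr(session, "task_config")
  if (is.null(config)) stop("pass the task_config")
  pre <- preprocess_session(session, ...)
  kept <- exclude_trials(pre, window = exclusion_window)
  kin <- decompose_session(kept)
  incl <- apply_session_inclusion(kin, config$prior_direction)
  summ <- condition_summaries(incl$kinematics)
  stats <- session_statistics(incl$kinematics, config)
  obs <- NULL
  if (fit_observer && nrow(summ) == 12) {
    obs <- fit_observer(summ, theta_p = config$prior_direction,
                        seed = fit_seed)
  }
  list(
    kinematics = incl$kinematics,
    inclusion = incl[c("retained", "n_prior_narrow", "n_prior_wide")],
    summaries = summ,
    statistics = stats,
    exclusions = attr(kept, "exclusion_log"),
    observer = obs,
    preprocessed = kept
  )
}

#' Simulate and analyse a multi-session experiment
#'
#' Orchestrates the full pipeline over `n_sessions` simulated sessions and
#' aggregates the group-level statistics: log-ratio t-tests of the bias
#' ratios and SD ratios, the bias-precision rank correlation, and the
#' session-average observer parameters. When `out_dir` is given, per-stage
#' artifacts (kinematics and summary CSVs, aggregate JSON report, manifest
#' with seeds and configuration) are written there; a rerun with the same
#' configuration and seed reproduces the report exactly.
#'
#' @param config A [task_config()].
#' @param params A [gen_params()].
#' @param n_sessions Number of sessions to simulate.
#' @param seed Master seed; session seeds are drawn from it.
#' @param fit_observer Whether to fit the observer model per session.
#' @param out_dir Optional output directory for artifacts.
#' @return List: `session_stats` (per-session tibble), `group` (list of
#'   group-level test tibbles), `observer_params` (per-session tibble or
#'   `NULL`), `seeds`, `retained`.
#' @export
run_pipeline <- function(config = task_config(), params = gen_params(),
                         n_sessions = 5, seed = 1L, fit_observer = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "task_config"), inherits(params, "gen_params"),
            n_sessions >= 1)
  session_seeds <- withr::with_seed(seed,
                                    sample.int(.Machine$integer.max, n_sessions))
  results <- purrr::map(session_seeds, function(s) {
    sess <- simulate_session(config, params, seed = s)
    analyze_session(sess, config, fit_observer = fit_observer, fit_seed = s)
  })

  session_stats <- purrr::imap_dfr(results, function(r, i) {
    bias <- tidyr::pivot_wider(r$statistics$bias,
                               names_from = c("block", "contrast"),
                               values_from = "ratio",
                               names_prefix = "bias_")
    sdr <- tidyr::pivot_wider(r$statistics$sd_ratio[c("contrast", "ratio")],
                              names_from = "contrast", values_from = "ratio",
                              names_prefix = "sd_ratio_")
    dplyr::bind_cols(
      tibble::tibble(session = i, seed = session_seeds[i],
                     retained = r$inclusion$retained,
                     n_prior_narrow = r$inclusion$n_prior_narrow,
                     n_prior_wide = r$inclusion$n_prior_wide),
      bias, sdr)
  })

  kept <- session_stats$retained
  group <- list()
  if (sum(kept) >= 5) {
    group$bias_narrow_low <- log_ratio_ttest(
      session_stats$bias_narrow_low[kept])
    group$bias_wide_low <- log_ratio_ttest(session_stats$bias_wide_low[kept])
    group$sd_ratio_low <- log_ratio_ttest(session_stats$sd_ratio_low[kept])
    group$sd_ratio_high <- log_ratio_ttest(session_stats$sd_ratio_high[kept])
  }
  if (sum(kept) >= 10) {
    bias_ratio_nw <- session_stats$bias_narrow_low[kept] /
      session_stats$bias_wide_low[kept]
    group$bias_precision_low <- bias_precision_correlation(
      bias_ratio_nw, session_stats$sd_ratio_low[kept])
  }

  observer_params <- NULL
  if (fit_observer) {
    observer_params <- purrr::imap_dfr(results, function(r, i) {
      if (is.null(r$observer)) return(tibble::tibble())
      dplyr::bind_cols(tibble::tibble(session = i), glance(r$observer))
    })
  }

  out <- list(session_stats = session_stats, group = group,
              observer_params = observer_params,
              seeds = session_seeds, retained = kept)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(session_stats, file.path(out_dir, "session_stats.csv"))
    kin_all <- purrr::imap_dfr(results, function(r, i)
      dplyr::mutate(r$kinematics, session = i))
    readr::write_csv(kin_all, file.path(out_dir, "kinematics.csv"))
    if (!is.null(observer_params) && nrow(observer_params) > 0)
      readr::write_csv(observer_params, file.path(out_dir, "observer_params.csv"))
    report <- list(
      group = purrr::map(group, as.list),
      n_sessions = n_sessions,
      n_retained = sum(kept)
    )
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("pursuitbayes")),
      master_seed = seed,
      session_seeds = session_seeds,
      task_config = unclass(config)[!vapply(config, is.function, logical(1))],
      gen_params = unclass(params)[!vapply(params, is.null, logical(1))]
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
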