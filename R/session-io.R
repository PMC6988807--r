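# On-disk session container: a metadata table plus the per-trial traces in
# long format, either as a two-CSV directory or a single Feather file.

#' Write a session to disk
#'
#' `format = "csv"` writes a directory with `metadata.csv` (one row per
#' trial) and `traces.csv` (long table: `trial_index`, `time_ms`,
#' `eye_h_deg`, `eye_v_deg`). `format = "feather"` writes one Arrow Feather
#' file containing the long trace table with the metadata columns joined on
#' (requires the arrow package).
#'
#' @param session Session tibble from [simulate_session()].
#' @param path Output directory (`csv`) or file (`feather`).
#' @param format `"csv"` or `"feather"`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("csv", "feather")) {
  format <- match.arg(format)
  meta_cols <- c("trial_index", "block", "block_rep", "contrast", "theta_s",
                 "theta_trial", "latency_ms", "gain", "saccade_ms",
                 "trial_seed")
  meta <- session[intersect(meta_cols, names(session))]
  traces <- dplyr::bind_rows(
    setNames(session$trace, session$trial_index), .id = "trial_index")
  traces$trial_index <- as.integer(traces$trial_index)
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(meta, file.path(path, "metadata.csv"))
    readr::write_csv(traces, file.path(path, "traces.csv"))
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'feather'")
    arrow::write_feather(dplyr::left_join(traces, meta, by = "trial_index"),
                         path)
  }
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path Directory (`csv`) or file (`feather`).
#' @param format `"csv"` or `"feather"`.
#' @return Session tibble with a `trace` list-column.
#' @export
read_session <- function(path, format = c("csv", "feather")) {
  format <- match.arg(format)
  if (format == "csv") {
    meta <- readr::read_csv(file.path(path, "metadata.csv"),
                            show_col_types = FALSE)
    traces <- readr::read_csv(file.path(path, "traces.csv"),
                              show_col_types = FALSE)
  } else {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the arrow package is required for format = 'feather'")
    long <- tibble::as_tibble(arrow::read_feather(path))
    trace_cols <- c("trial_index", "time_ms", "eye_h_deg", "eye_v_deg")
    traces <- long[trace_cols]
    meta <- dplyr::distinct(long[setdiff(names(long),
                                         setdiff(trace_cols, "trial_index"))])
  }
  tr_split <- split(traces[c("time_ms", "eye_h_deg", "eye_v_deg")],
                    traces$trial_index)
  meta$trace <- unname(tr_split[as.character(meta$trial_index)])
  meta
}
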