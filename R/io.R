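#' Write a session's trial table to CSV
#'
#' One row per trial with the documented columns (\code{trial_index},
#' \code{block}, \code{arrow}, \code{is_stop}, \code{condition},
#' \code{sound_id}, \code{ssd}, \code{go_rt}, \code{response},
#' \code{outcome}).
#'
#' @param session an \code{"sst_session"} or trial-table data.frame.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_trial_table <- function(session, path) {
  utils::write.csv(as_trial_table(session), path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by \code{\link{write_trial_table}}
#'
#' @param path CSV file path.
#' @return a trial-table data.frame usable by the behavioural functions.
#' @export
read_trial_table <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("trial_index", "is_stop", "condition", "ssd", "go_rt", "outcome")
  missing <- setdiff(needed, names(tr))
  if (length(missing))
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  tr$is_stop <- as.logical(tr$is_stop)
  tr
}

#' Write a recording's event markers as a tab-separated file
#'
#' Columns: \code{sample}, \code{code}, \code{trial_index}.
#'
#' @param recording an \code{"eeg_recording"}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_event_table <- function(recording, path) {
  utils::write.table(recording$events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Save pipeline settings as YAML
#'
#' Serializes the scalar settings of a pipeline configuration (cohort size,
#' master seed, session design, race-model population, noise, analysis
#' options). Component definitions and the ERP population are rebuilt from
#' their constructors on read, so custom templates or cell-mean overrides are
#' not round-tripped; pass those programmatically instead.
#'
#' @param config an \code{"sst_pipeline_config"}.
#' @param path output YAML path.
#' @return invisibly, \code{path}.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- list(
    n_subjects = config$n_subjects,
    master_seed = config$master_seed,
    min_per_bin = config$min_per_bin,
    include_go_errors = config$include_go_errors,
    session = unclass(config$session),
    population = unclass(config$population),
    noise = unclass(config$noise),
    erp_links = list(
      level_beta_p3 = config$erp$level_link$beta_p3,
      level_beta_n1 = config$erp$level_link$beta_n1,
      level_predictor_r = config$erp$level_link$predictor_r,
      diff_beta_p3 = config$erp$diff_link$beta_p3,
      diff_beta_n1 = config$erp$diff_link$beta_n1,
      diff_predictor_r = config$erp$diff_link$predictor_r))
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Load pipeline settings from YAML
#'
#' @param path YAML file written by \code{\link{write_pipeline_config}}.
#' @return an \code{"sst_pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  flat <- yaml::read_yaml(path)
  el <- flat$erp_links
  pipeline_config(
    n_subjects = flat$n_subjects,
    master_seed = flat$master_seed,
    session = do.call(session_config, flat$session),
    population = do.call(cohort_population, flat$population),
    erp = erp_population(
      level_beta_p3 = el$level_beta_p3, level_beta_n1 = el$level_beta_n1,
      level_predictor_r = el$level_predictor_r,
      diff_beta_p3 = el$diff_beta_p3, diff_beta_n1 = el$diff_beta_n1,
      diff_predictor_r = el$diff_predictor_r),
    noise = do.call(noise_config, flat$noise),
    min_per_bin = flat$min_per_bin,
    include_go_errors = flat$include_go_errors)
}
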