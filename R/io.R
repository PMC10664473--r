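# Delimited-text I/O for cohorts and YAML scenario configs.

#' Read and write long-format cohort data
#'
#' Cohorts are stored as CSV with one row per subject-visit and columns
#' `subject_id`, `arm`, `time`, `y` (header required).
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated tibble.
#' @export
read_cohort <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("subject_id", "arm", "time", "y")
  if (!all(req %in% names(d))) {
    abort("Cohort CSV must have columns subject_id, arm, time, y.")
  }
  dplyr::as_tibble(d[req])
}

#' @rdname read_cohort
#' @param data Long cohort tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data[c("subject_id", "arm", "time", "y")], path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' Accepts the same fields as [scenario_config()] (with `obs_schedule` /
#' `trial_schedule` given as lists or comma-separated strings); unknown
#' fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(scenario_config)), "")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    abort(paste0("Unknown scenario fields: ", paste(bad, collapse = ", ")))
  }
  for (f in c("obs_schedule", "trial_schedule")) {
    if (!is.null(raw[[f]]) && is.character(raw[[f]])) {
      raw[[f]] <- as.numeric(strsplit(raw[[f]], ",")[[1]])
    }
  }
  do.call(scenario_config, raw)
}
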