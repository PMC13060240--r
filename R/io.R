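# Plain-text I/O: long-format CSV data, truth sidecars, YAML configs.
# Ages are carried in months everywhere; the year-to-month conversion factor
# is exactly 12 and applied only here at ingestion, never downstream.

MONTHS_PER_YEAR <- 12

#' Write a synthetic cohort to plain-text files
#'
#' Writes `data.csv` (long format: `subject_id`, `age_months`,
#' `aligned_age_months`, `outcome`, `variant`, `session`, `value`,
#' `n_trials`), `markers.csv` (`subject_id`, `marker_age`), `truth.csv`
#' (latent curves on the analysis grid: `outcome`, `aligned_age_months`,
#' `value`) and `config.yaml` mirroring the [cohort_config()] field names.
#'
#' @param cohort a [gen_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "traj_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("data.csv", "markers.csv", "truth.csv",
                            "config.yaml"))
  write.csv(cohort$data, paths[1], row.names = FALSE)
  markers <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    marker_age = vapply(cohort$subjects, `[[`, 1.0, "marker_age"))
  write.csv(markers, paths[2], row.names = FALSE)
  truth <- do.call(rbind, lapply(names(cohort$truths), function(nm)
    data.frame(outcome = nm, cohort$truths[[nm]])))
  write.csv(truth, paths[3], row.names = FALSE)
  yaml::write_yaml(config_to_list(cohort$config), paths[4])
  invisible(paths)
}

#' Read a long-format trajectory dataset
#'
#' Accepts the schema written by [write_cohort()] or user data with at least
#' `subject_id`, `outcome`, `value` and one of `aligned_age_months` or
#' `age_months`. Unknown columns are preserved and ignored.
#'
#' @param path CSV file.
#' @return tibble.
#' @export
read_long_data <- function(path) {
  data <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("subject_id", "outcome", "value")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data file lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(c("aligned_age_months", "age_months") %in% names(data)))
    stop("data file needs `aligned_age_months` or `age_months`", call. = FALSE)
  data
}

# cohort_config <-> plain list (YAML-safe), field names mirrored exactly
config_to_list <- function(config) {
  list(n_subjects = config$n_subjects, marker_mean = config$marker_mean,
       marker_sd = config$marker_sd, age_start = config$age_start,
       age_end = config$age_end, visit_interval = config$visit_interval,
       seed = config$seed,
       outcome_specs = lapply(unname(config$outcome_specs), function(s) {
         out <- list(name = s$name, family = s$family, role = s$role,
                     shape = unclass(s$shape),
                     random_intercept_sd = s$random_intercept_sd,
                     random_slope_sd = s$random_slope_sd,
                     sessions_per_visit = s$sessions_per_visit)
         if (!is.null(s$variant_offsets))
           out$variant_offsets <- as.list(s$variant_offsets)
         if (!is.null(s$n_trials)) out$n_trials <- s$n_trials
         if (!is.null(s$noise_sd)) out$noise_sd <- s$noise_sd
         out
       }))
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file with fields mirroring [cohort_config()].
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  specs <- lapply(x$outcome_specs, function(s) {
    sh <- s$shape
    args <- list(name = s$name, family = s$family, role = s$role,
                 shape = logistic_shape(sh$lower, sh$upper, sh$midpoint,
                                        sh$scale))
    for (f in c("random_intercept_sd", "random_slope_sd",
                "sessions_per_visit", "n_trials", "noise_sd"))
      if (!is.null(s[[f]])) args[[f]] <- s[[f]]
    if (!is.null(s$variant_offsets))
      args$variant_offsets <- unlist(s$variant_offsets)
    do.call(outcome_spec, args)
  })
  cohort_config(n_subjects = x$n_subjects, marker_mean = x$marker_mean,
                marker_sd = x$marker_sd, age_start = x$age_start,
                age_end = x$age_end, visit_interval = x$visit_interval,
                seed = x$seed, outcome_specs = specs)
}
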