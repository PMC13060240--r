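#' Configuration for an end-to-end pipeline run
#'
#' Bundles the cohort definition and every analysis parameter so a run is
#' fully determined by one object. The master `seed` overrides the cohort
#' seed and derives all downstream streams (posterior simulation,
#' permutations) by stable hashing, so rerunning an identical config yields
#' byte-identical outputs.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort (or the
#'   schema of supplied data).
#' @param k spline basis dimension.
#' @param n_grid maturation-grid size (default 100).
#' @param alpha level for FDR screening and simultaneous derivative bands.
#' @param n_perm maxT permutations.
#' @param n_sim posterior draws for derivative bands.
#' @param fdr if `TRUE`, derivative windows are computed only for outcomes
#'   whose BH-adjusted smooth p-value is below `alpha`.
#' @param seed master integer seed recorded in every artifact.
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), k = 5L, n_grid = 100L,
                       alpha = 0.05, n_perm = 1000L, n_sim = 10000L,
                       fdr = TRUE, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  assert_scalar_num(seed, "seed")
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, k = as.integer(k),
                 n_grid = as.integer(n_grid), alpha = alpha,
                 n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
                 fdr = isTRUE(fdr), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full trajectory-alignment pipeline
#'
#' Executes, in order: cohort generation (or reuse of a supplied cohort),
#' variant-pooled behavioral performance, per-outcome penalized-spline mixed
#' fits with BH correction across outcomes, predictions on the fixed
#' maturation grid whose bounds come from the behavioral data's earliest and
#' latest aligned ages, derivative-band change windows for significant
#' outcomes, similarity of every tract trajectory against the pooled
#' behavioral reference (maxT families per tract metric, FA and RD
#' separately), a behavior-vs-behavior positive control, and family medians.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-generated `traj_cohort` (must match the
#'   config's cohort definition); by default the cohort is generated from
#'   `config$cohort`.
#' @param out_dir optional directory; when given, all tables plus a manifest
#'   are written as CSV/YAML and the manifest lists every file with its MD5.
#' @return list with class `pipeline_run`: `fits_summary`, `curves` (named
#'   list of [predict_grid()] results), `windows`, `similarity` (per-family
#'   tibbles), `medians`, `control`, `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...)
    message(sprintf("[trajalign %6.1fs] ",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            sprintf(fmt, ...))

  if (is.null(cohort)) {
    log_stage("simulate: %d subjects, %d outcomes, seed %d",
              config$cohort$n_subjects, length(config$cohort$outcome_specs),
              config$seed)
    cohort <- gen_cohort(config$cohort)
  }
  stopifnot(inherits(cohort, "traj_cohort"))
  if (any(cohort$n_clamped > 0))
    log_stage("warning: %d outcome(s) had clamped session probabilities",
              sum(cohort$n_clamped > 0))

  specs <- cohort$config$outcome_specs
  roles <- vapply(specs, `[[`, "", "role")
  behav <- names(roles)[roles == "behavior"]
  if (length(behav) != 1L)
    stop("pipeline requires exactly one behavior-role outcome", call. = FALSE)

  log_stage("align/pool: behavioral outcome '%s'", behav)
  pooled <- pool_performance(cohort$data[cohort$data$outcome == behav, ])
  analysis_data <- rbind(cohort$data[cohort$data$outcome != behav, ], pooled)
  fit_names <- c("behavior_pooled", names(roles)[roles != "behavior"])
  fit_roles <- c("behavior", unname(roles[roles != "behavior"]))

  log_stage("fit: %d outcomes, k = %d, REML", length(fit_names), config$k)
  fits <- lapply(fit_names, function(nm)
    fit_smooth(analysis_data, nm, k = config$k))
  names(fits) <- fit_names
  p_smooth <- vapply(fits, `[[`, 1.0, "p_smooth")
  p_fdr <- fdr_adjust(p_smooth)

  # grid bounds: earliest/latest aligned behavioral ages, shared by all curves
  glo <- min(pooled$aligned_age_months)
  ghi <- max(pooled$aligned_age_months)
  log_stage("predict: %d-point grid on [%.1f, %.1f] aligned months",
            config$n_grid, glo, ghi)
  curves <- withCallingHandlers(
    lapply(fits, predict_grid, grid_lo = glo, grid_hi = ghi,
           n_grid = config$n_grid),
    warning = function(w) invokeRestart("muffleWarning"))

  win_names <- if (config$fdr) fit_names[p_fdr < config$alpha] else fit_names
  log_stage("windows: %d outcome(s) pass FDR at alpha = %g",
            length(win_names), config$alpha)
  windows <- lapply(win_names, function(nm)
    derivative_windows(fits[[nm]], curves[[nm]], n_sim = config$n_sim,
                       alpha = config$alpha,
                       seed = stream_seed(config$seed, paste0("windows:", nm))))
  names(windows) <- win_names

  fits_summary <- tibble(
    outcome = fit_names, role = fit_roles,
    lambda = vapply(fits, `[[`, 1.0, "lambda"),
    scale = vapply(fits, `[[`, 1.0, "scale"),
    n_obs = vapply(fits, `[[`, 1L, "n_obs"),
    argmin_age = vapply(curves, `[[`, 1.0, "argmin_age"),
    argmax_age = vapply(curves, `[[`, 1.0, "argmax_age"),
    p_smooth = unname(p_smooth), p_fdr = unname(p_fdr))

  ref_curve <- curves[["behavior_pooled"]]
  similarity <- list()
  for (fam in c("tract-FA", "tract-RD")) {
    members <- fit_names[fit_roles == fam]
    if (!length(members)) next
    famkey <- sub("tract-", "", fam)
    log_stage("similarity: %s family, %d tracts, %d permutations",
              famkey, length(members), config$n_perm)
    similarity[[famkey]] <- curve_similarity(
      ref_curve, setNames(lapply(members, function(nm) curves[[nm]]), members),
      n_perm = config$n_perm,
      seed = stream_seed(config$seed, paste0("maxT:", famkey)))
  }
  medians <- lapply(similarity, family_summary)
  control <- list(
    r = trajectory_corr(ref_curve$values, ref_curve$values),
    rmse = trajectory_rmse(shift_abs(zscore_curve(ref_curve$values)),
                           shift_abs(zscore_curve(ref_curve$values))))

  run <- structure(list(fits_summary = fits_summary, fits = fits,
                        curves = curves, windows = windows,
                        similarity = similarity, medians = medians,
                        control = control, cohort = cohort, config = config,
                        manifest = NULL),
                   class = "pipeline_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  log_stage("done")
  run
}

# Serialize a pipeline run to CSVs plus a manifest with file hashes.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort_paths <- write_cohort(run$cohort, out_dir)
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    write.csv(df, p, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }
  emit(run$fits_summary, "fits.csv")
  curves_df <- do.call(rbind, lapply(run$curves, function(cv)
    data.frame(outcome = cv$outcome, aligned_age_months = cv$grid,
               value = cv$values, ci_lower = cv$ci_lower,
               ci_upper = cv$ci_upper, se = cv$se)))
  emit(curves_df, "curves.csv")
  win_df <- do.call(rbind, c(lapply(run$windows, function(w)
    if (nrow(w$intervals)) data.frame(outcome = w$outcome, w$intervals)
    else NULL), make.row.names = FALSE))
  if (is.null(win_df))
    win_df <- data.frame(outcome = character(), start = numeric(),
                         end = numeric(), sign = integer())
  emit(win_df, "windows.csv")
  for (fam in names(run$similarity))
    emit(run$similarity[[fam]], sprintf("similarity_%s.csv", fam))
  med_df <- do.call(rbind, lapply(names(run$medians), function(fam)
    data.frame(family = fam,
               median_abs_r = run$medians[[fam]]$median_abs_r,
               median_r = run$medians[[fam]]$median_r,
               median_rmse = run$medians[[fam]]$median_rmse,
               n_pairs = nrow(run$similarity[[fam]]))))
  if (length(run$medians)) emit(med_df, "medians.csv")
  emit(data.frame(pair = "behavior_pooled:behavior_pooled",
                  r = run$control$r, rmse = run$control$rmse),
       "control.csv")
  files <- c(cohort_paths, unlist(paths))
  manifest <- list(seed = run$config$seed,
                   package = "trajalign",
                   version = as.character(utils::packageVersion("trajalign")),
                   parameters = list(k = run$config$k,
                                     n_grid = run$config$n_grid,
                                     alpha = run$config$alpha,
                                     n_perm = run$config$n_perm,
                                     n_sim = run$config$n_sim,
                                     fdr = run$config$fdr),
                   files = as.list(setNames(unname(tools::md5sum(files)),
                                            basename(files))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d outcomes fitted, seed %d\n",
              nrow(x$fits_summary), x$config$seed))
  for (fam in names(x$medians))
    cat(sprintf("  %s family: median |r| = %.4f, median r = %.4f, median RMSE = %.4f (n = %d)\n",
                fam, x$medians[[fam]]$median_abs_r, x$medians[[fam]]$median_r,
                x$medians[[fam]]$median_rmse, nrow(x$similarity[[fam]])))
  cat(sprintf("  control (behavior vs itself): r = %g, RMSE = %g\n",
              x$control$r, x$control$rmse))
  invisible(x)
}
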