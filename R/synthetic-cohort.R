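#' Parameterized saturating (4-parameter logistic) maturation shape
#'
#' Latent maturation curves are modelled as four-parameter logistic functions
#' of aligned age (months relative to the maturation marker): steep gains
#' around `midpoint` saturating towards `upper`. A falling curve (e.g. radial
#' diffusivity, which decreases with myelination) is encoded with
#' `upper < lower`.
#'
#' @param lower lower asymptote (value at very young aligned age), outcome units.
#' @param upper upper asymptote (mature value), outcome units. `upper < lower`
#'   gives a non-increasing (RD-like) curve.
#' @param midpoint aligned age (months) of steepest change.
#' @param scale logistic scale (months); smaller is steeper. Must be > 0.
#' @return an object of class `traj_shape`.
#' @examples
#' sh <- logistic_shape(0.45, 0.92, midpoint = -8, scale = 5)
#' eval_shape(sh, c(-24, 0, 17))
#' @export
logistic_shape <- function(lower, upper, midpoint, scale) {
  assert_scalar_num(lower, "lower")
  assert_scalar_num(upper, "upper")
  assert_scalar_num(midpoint, "midpoint")
  assert_scalar_num(scale, "scale", lower = .Machine$double.eps)
  structure(list(lower = lower, upper = upper, midpoint = midpoint,
                 scale = scale), class = "traj_shape")
}

#' Evaluate a maturation shape on aligned ages
#'
#' @param shape a [logistic_shape()] object.
#' @param aligned_age numeric vector of aligned ages (months).
#' @return numeric vector of latent values.
#' @export
eval_shape <- function(shape, aligned_age) {
  stopifnot(inherits(shape, "traj_shape"))
  shape$lower + (shape$upper - shape$lower) *
    plogis((aligned_age - shape$midpoint) / shape$scale)
}

#' Specification of one synthetic outcome
#'
#' @param name outcome label (must be unique within a cohort).
#' @param family one of `"binomial-performance"` (session percent-correct from
#'   binomial trial counts), `"gaussian-rate"` (session-mean firing rate) or
#'   `"gaussian-tract"` (per-visit white-matter scalar such as FA or RD).
#' @param shape latent maturation curve, a [logistic_shape()]. For
#'   binomial-performance it is on the probability scale and must stay within
#'   \[0, 1\] (before variant offsets).
#' @param role analysis role: `"behavior"`, `"neural"`, `"tract-FA"` or
#'   `"tract-RD"`. Drives grid choice and similarity families downstream.
#' @param variant_offsets named numeric vector of additive task-variant
#'   difficulty shifts on the logit scale (binomial only). The default encodes
#'   the overlap > zero-gap > gap ease ordering.
#' @param n_trials trials per session (binomial only).
#' @param noise_sd observation noise SD, outcome units (gaussian only).
#' @param random_intercept_sd,random_slope_sd SDs of subject-level random
#'   intercept and random slope on aligned age. For binomial-performance these
#'   act on the probability scale (per month for the slope).
#' @param sessions_per_visit sessions generated at each visit (1 for tract
#'   scalars, which come from a single scan).
#' @return an object of class `outcome_spec`.
#' @export
outcome_spec <- function(name,
                         family = c("binomial-performance", "gaussian-rate",
                                    "gaussian-tract"),
                         shape,
                         role = c("behavior", "neural", "tract-FA", "tract-RD"),
                         variant_offsets = c(overlap = 0.4, `zero-gap` = 0,
                                             gap = -0.4),
                         n_trials = 120L,
                         noise_sd = NULL,
                         random_intercept_sd = 0,
                         random_slope_sd = 0,
                         sessions_per_visit = NULL) {
  family <- match.arg(family)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            inherits(shape, "traj_shape"))
  binom <- family == "binomial-performance"
  if (binom) {
    if (shape$lower < 0 || shape$lower > 1 || shape$upper < 0 || shape$upper > 1)
      stop("binomial-performance shape asymptotes must lie in [0, 1]",
           call. = FALSE)
    assert_scalar_num(n_trials, "n_trials", lower = 1)
    if (is.null(names(variant_offsets)) || any(!nzchar(names(variant_offsets))))
      stop("variant_offsets must be a named numeric vector", call. = FALSE)
  } else {
    if (is.null(noise_sd))
      stop("gaussian families require `noise_sd`", call. = FALSE)
    assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  }
  if (family == "gaussian-tract" && role %in% c("behavior", "neural"))
    stop("gaussian-tract outcomes must carry a tract role", call. = FALSE)
  assert_scalar_num(random_intercept_sd, "random_intercept_sd", lower = 0)
  assert_scalar_num(random_slope_sd, "random_slope_sd", lower = 0)
  if (is.null(sessions_per_visit))
    sessions_per_visit <- if (family == "gaussian-tract") 1L else 19L
  assert_scalar_num(sessions_per_visit, "sessions_per_visit", lower = 1)
  structure(list(name = name, family = family, shape = shape, role = role,
                 variant_offsets = if (binom) variant_offsets else NULL,
                 n_trials = if (binom) as.integer(n_trials) else NULL,
                 noise_sd = if (binom) NULL else noise_sd,
                 random_intercept_sd = random_intercept_sd,
                 random_slope_sd = random_slope_sd,
                 sessions_per_visit = as.integer(sessions_per_visit)),
            class = "outcome_spec")
}

#' Check the monotonicity contract of a tract shape
#'
#' FA-like (`tract-FA`) latent curves must be non-decreasing on a dense aligned
#' age grid and RD-like (`tract-RD`) curves non-increasing.
#'
#' @param spec an [outcome_spec()].
#' @param from,to aligned-age range (months) to check on.
#' @param n dense-grid size.
#' @return `TRUE` (invisibly) or an error.
#' @export
check_shape_monotone <- function(spec, from = -48, to = 48, n = 2001L) {
  stopifnot(inherits(spec, "outcome_spec"))
  v <- eval_shape(spec$shape, seq(from, to, length.out = n))
  d <- diff(v)
  ok <- switch(spec$role,
               `tract-FA` = all(d >= -1e-12),
               `tract-RD` = all(d <= 1e-12),
               TRUE)
  if (!isTRUE(ok))
    stop(sprintf("shape of '%s' violates the %s monotonicity contract",
                 spec$name, spec$role), call. = FALSE)
  invisible(TRUE)
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: four subjects
#' followed quarterly across roughly 34–75 months of age, with a biological
#' mid-adolescence marker (tibial epiphyseal closure) at 57.9 ± 3.6 months.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param marker_mean,marker_sd mean and SD (months) of the Normal from which
#'   per-subject maturation-marker ages are drawn.
#' @param age_start,age_end first and last chronological visit age (months).
#' @param visit_interval spacing between visits (months); quarterly = 3.
#' @param seed master integer seed; identical configs (including seed)
#'   regenerate byte-identical cohorts. Per-outcome streams are derived by a
#'   stable hash of (seed, outcome name), so adding an outcome never perturbs
#'   the realizations of existing ones.
#' @param outcome_specs list of [outcome_spec()] objects.
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(outcome_specs = default_outcome_specs(n_tracts = 4))
#' @export
cohort_config <- function(n_subjects = 4L, marker_mean = 57.9, marker_sd = 3.6,
                          age_start = 34, age_end = 75, visit_interval = 3,
                          seed = 1L, outcome_specs = default_outcome_specs()) {
  assert_scalar_num(n_subjects, "n_subjects", lower = 1)
  assert_scalar_num(marker_mean, "marker_mean", lower = 0)
  assert_scalar_num(marker_sd, "marker_sd", lower = 0)
  assert_scalar_num(age_start, "age_start")
  assert_scalar_num(age_end, "age_end")
  if (age_start >= age_end) stop("age_start must be < age_end", call. = FALSE)
  if (!is.numeric(visit_interval) || visit_interval <= 0)
    stop("visit_interval must be > 0", call. = FALSE)
  assert_scalar_num(seed, "seed")
  stopifnot(is.list(outcome_specs),
            all(vapply(outcome_specs, inherits, TRUE, "outcome_spec")))
  nm <- vapply(outcome_specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("outcome names must be unique", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 marker_mean = marker_mean, marker_sd = marker_sd,
                 age_start = age_start, age_end = age_end,
                 visit_interval = visit_interval, seed = as.integer(seed),
                 outcome_specs = setNames(outcome_specs, nm)),
            class = "cohort_config")
}

#' Default outcome roster: behavior, firing rate, FA and RD tract batteries
#'
#' The behavioral outcome rises steeply just before the maturation marker
#' (gains concentrated in early adolescence) from ~45% to ~92% correct;
#' firing rate rises through the marker age; the 53-tract FA battery rises
#' with per-tract midpoints spread through adolescence, and the RD battery
#' mirrors it downward (units of 10^-3 mm^2/s).
#'
#' @param n_tracts tracts per battery (53 mirrors a whole-brain tractography
#'   atlas of long-distance tracts).
#' @param tract_noise_sd observation noise SD for FA (RD uses 1.5x).
#' @return named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function(n_tracts = 53L, tract_noise_sd = 0.008) {
  specs <- list(
    outcome_spec("antisaccade", "binomial-performance",
                 logistic_shape(0.45, 0.92, midpoint = -8, scale = 5),
                 role = "behavior", n_trials = 120L,
                 random_intercept_sd = 0.03, random_slope_sd = 0.0015),
    outcome_spec("pfc_rate", "gaussian-rate",
                 logistic_shape(12, 32, midpoint = 0, scale = 8),
                 role = "neural", noise_sd = 3,
                 random_intercept_sd = 0.5, random_slope_sd = 0.01)
  )
  c(specs,
    tract_battery_specs(n_tracts, type = "FA", noise_sd = tract_noise_sd),
    tract_battery_specs(n_tracts, type = "RD", noise_sd = 1.5 * tract_noise_sd))
}

#' Battery of white-matter tract outcome specs
#'
#' Per-tract latent curves share the saturating maturation motif but differ
#' deterministically in midpoint (evenly spread over \[-12, 6\] aligned
#' months), steepness and asymptote separation, so the battery spans realistic
#' tract-to-tract heterogeneity without extra random streams. FA-type curves
#' are non-decreasing; RD-type curves are their non-increasing mirror.
#'
#' @param n number of tracts.
#' @param type `"FA"` (rising, dimensionless, ~0.35 to ~0.52) or `"RD"`
#'   (falling, ~1.05 to ~0.80 in 10^-3 mm^2/s).
#' @param noise_sd per-observation noise SD.
#' @return list of [outcome_spec()] objects named `<type>_tract_01`, ...
#' @export
tract_battery_specs <- function(n = 53L, type = c("FA", "RD"),
                                noise_sd = 0.008) {
  type <- match.arg(type)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  mids <- if (n == 1L) 0 else seq(-12, 6, length.out = n)
  scales <- 4 + 3 * (seq_len(n) %% 4) / 3        # 4..7 months, cycling
  span <- 0.12 + 0.06 * ((seq_len(n) %% 5) / 4)  # asymptote separation
  lapply(seq_len(n), function(i) {
    if (type == "FA") {
      sh <- logistic_shape(0.35, 0.35 + span[i], mids[i], scales[i])
      ri <- 0.01; rs <- 2e-4
    } else {
      sh <- logistic_shape(1.05, 1.05 - 1.8 * span[i], mids[i], scales[i])
      ri <- 0.02; rs <- 4e-4
    }
    outcome_spec(sprintf("%s_tract_%02d", type, i), "gaussian-tract", sh,
                 role = paste0("tract-", type), noise_sd = noise_sd,
                 random_intercept_sd = ri, random_slope_sd = rs)
  })
}

#' Generate subject timelines
#'
#' Draws each subject's maturation-marker age from
#' Normal(`marker_mean`, `marker_sd`^2) and lays out chronological visit ages
#' from `age_start` to `age_end` at `visit_interval` spacing. Deterministic
#' under the config seed.
#'
#' @param config a [cohort_config()].
#' @return list of [subject_timeline()] objects.
#' @export
gen_subjects <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  visits <- seq(config$age_start, config$age_end, by = config$visit_interval)
  markers <- with_seed(stream_seed(config$seed, "subjects"),
                       rnorm(config$n_subjects, config$marker_mean,
                             config$marker_sd))
  markers <- pmax(markers, .Machine$double.eps)  # marker_age > 0 contract
  lapply(seq_len(config$n_subjects), function(i)
    subject_timeline(sprintf("S%02d", i), visits, markers[i]))
}

#' Generate one outcome's longitudinal dataset
#'
#' Binomial-performance outcomes emit per-session percent-correct
#' `100 * successes / n_trials` with
#' `successes ~ Binomial(n_trials, p(aligned age) + subject effects)`, per
#' task variant with additive logit difficulty offsets. Gaussian outcomes emit
#' `shape(aligned age) + b0_subject + b1_subject * aligned age + N(0, noise_sd)`.
#' The latent truth curve (for binomial: the variant-pooled percent scale) is
#' returned alongside the data for recovery testing.
#'
#' Probabilities pushed outside \[0, 1\] by subject effects are clamped; the
#' clamp count is recorded and reported with a warning, never silently.
#'
#' @param subjects list of [subject_timeline()] objects.
#' @param spec an [outcome_spec()].
#' @param seed integer seed for this outcome's stream.
#' @param truth_n grid size of the stored latent truth curve.
#' @return list with class `traj_outcome`: `data` (tibble with columns
#'   `subject_id`, `age_months`, `aligned_age_months`, `outcome`, `variant`,
#'   `session`, `value`, `n_trials`), `truth` (tibble `aligned_age_months`,
#'   `value`), `n_clamped`.
#' @export
gen_outcome <- function(subjects, spec, seed, truth_n = 100L) {
  stopifnot(is.list(subjects), length(subjects) >= 1L,
            all(vapply(subjects, inherits, TRUE, "subject_timeline")),
            inherits(spec, "outcome_spec"))
  binom <- spec$family == "binomial-performance"
  variants <- if (binom) names(spec$variant_offsets) else NA_character_
  n_clamped <- 0L

  rows <- with_seed(seed, {
    lapply(subjects, function(subj) {
      b0 <- rnorm(1, 0, spec$random_intercept_sd)
      b1 <- rnorm(1, 0, spec$random_slope_sd)
      aligned <- align_ages(subj)
      latent <- eval_shape(spec$shape, aligned)
      per_visit <- lapply(seq_along(aligned), function(j) {
        a <- aligned[j]
        if (binom) {
          p0 <- pmin(pmax(latent[j], 1e-12), 1 - 1e-12)
          p_var <- plogis(qlogis(p0) + spec$variant_offsets) + b0 + b1 * a
          clamped <- sum(p_var < 0 | p_var > 1)
          if (clamped > 0) n_clamped <<- n_clamped + clamped
          p_var <- pmin(pmax(p_var, 0), 1)
          succ <- rbinom(length(variants) * spec$sessions_per_visit,
                         spec$n_trials, rep(p_var, spec$sessions_per_visit))
          data.frame(subject_id = subj$subject_id,
                     age_months = subj$visit_ages[j], aligned_age_months = a,
                     variant = rep(variants, spec$sessions_per_visit),
                     session = rep(seq_len(spec$sessions_per_visit),
                                   each = length(variants)),
                     value = 100 * succ / spec$n_trials,
                     n_trials = spec$n_trials)
        } else {
          mu <- latent[j] + b0 + b1 * a
          val <- mu + rnorm(spec$sessions_per_visit, 0, spec$noise_sd)
          data.frame(subject_id = subj$subject_id,
                     age_months = subj$visit_ages[j], aligned_age_months = a,
                     variant = NA_character_,
                     session = seq_len(spec$sessions_per_visit),
                     value = val, n_trials = NA_integer_)
        }
      })
      do.call(rbind, per_visit)
    })
  })
  data <- do.call(rbind, rows)
  data$outcome <- spec$name
  data <- as_tibble(data[, c("subject_id", "age_months", "aligned_age_months",
                             "outcome", "variant", "session", "value",
                             "n_trials")])
  ar <- range(data$aligned_age_months)
  grid <- seq(ar[1], ar[2], length.out = truth_n)
  tv <- eval_shape(spec$shape, grid)
  if (binom) {
    tv <- pmin(pmax(tv, 1e-12), 1 - 1e-12)
    tv <- 100 * rowMeans(plogis(outer(qlogis(tv), spec$variant_offsets, `+`)))
  }
  if (n_clamped > 0)
    warning(sprintf("outcome '%s': %d session probabilities clamped to [0, 1]",
                    spec$name, n_clamped), call. = FALSE)
  structure(list(data = data,
                 truth = tibble(aligned_age_months = grid, value = tv),
                 n_clamped = n_clamped, spec = spec),
            class = "traj_outcome")
}

#' Generate a full synthetic cohort
#'
#' Draws subject timelines and every configured outcome, each from its own
#' seed stream derived by stable hashing of (seed, outcome name).
#'
#' @param config a [cohort_config()].
#' @return list with class `traj_cohort`: `subjects`, `data` (all outcomes,
#'   long format), `truths` (named list of truth tibbles), `n_clamped`
#'   (named), `config`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- gen_subjects(config)
  draws <- lapply(config$outcome_specs, function(spec)
    gen_outcome(subjects, spec,
                seed = stream_seed(config$seed, paste0("outcome:", spec$name))))
  data <- do.call(rbind, lapply(draws, `[[`, "data"))
  attr(data, "row.names") <- seq_len(nrow(data))
  structure(list(
    subjects = subjects,
    data = data,
    truths = lapply(draws, `[[`, "truth"),
    n_clamped = vapply(draws, `[[`, 0L, "n_clamped"),
    config = config), class = "traj_cohort")
}
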