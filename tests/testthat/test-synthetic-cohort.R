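test_that("marker ages follow the configured Normal and degenerate cleanly", {
  # large-cohort sample mean within 3 SE of the 57.9-month marker mean
  cfg <- cohort_config(n_subjects = 200L, seed = 42L,
                       outcome_specs = default_outcome_specs(n_tracts = 1))
  subj <- gen_subjects(cfg)
  markers <- vapply(subj, `[[`, 1.0, "marker_age")
  expect_lt(abs(mean(markers) - 57.9), 3 * 3.6 / sqrt(200))
  expect_gt(sd(markers), 0)

  # marker_sd = 0: every subject shares marker_age = marker_mean
  cfg0 <- cohort_config(n_subjects = 5L, marker_sd = 0, seed = 1L,
                        outcome_specs = default_outcome_specs(n_tracts = 1))
  expect_true(all(vapply(gen_subjects(cfg0), `[[`, 1.0, "marker_age") == 57.9))

  # visit layout respects start/end/interval
  expect_equal(subj[[1]]$visit_ages, seq(34, 75, by = 3))
  expect_error(cohort_config(visit_interval = 0), "visit_interval")
})

test_that("identical configs regenerate identical cohorts; seeds move noise only", {
  cfg <- cohort_config(seed = 9L,
                       outcome_specs = default_outcome_specs(n_tracts = 2))
  a <- gen_cohort(cfg)
  b <- gen_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$truths, b$truths)

  # a different seed moves the noise realization but not the latent truth
  # function: each stored truth curve is the exact evaluation of the same
  # maturation shape on its cohort's observed aligned range
  r1 <- gen_cohort(make_rate_config(seed = 9L))
  r2 <- gen_cohort(make_rate_config(seed = 10L))
  expect_false(identical(r1$data$value, r2$data$value))
  shape <- make_rate_config(seed = 1L)$outcome_specs[[1]]$shape
  expect_equal(r1$truths$pfc_rate$value,
               eval_shape(shape, r1$truths$pfc_rate$aligned_age_months),
               tolerance = 1e-12)
  expect_equal(r2$truths$pfc_rate$value,
               eval_shape(shape, r2$truths$pfc_rate$aligned_age_months),
               tolerance = 1e-12)
})

test_that("adding an outcome never perturbs existing outcome streams", {
  base <- default_outcome_specs(n_tracts = 1)
  extra <- c(base, list(outcome_spec("extra_rate", "gaussian-rate",
                                     logistic_shape(5, 9, 0, 6),
                                     role = "neural", noise_sd = 1)))
  a <- gen_cohort(cohort_config(seed = 3L, outcome_specs = base))
  b <- gen_cohort(cohort_config(seed = 3L, outcome_specs = extra))
  keep <- b$data$outcome %in% unique(a$data$outcome)
  expect_identical(a$data, b$data[keep, ])
})

test_that("gaussian outcomes reduce to the latent shape in the noiseless limit", {
  cfg <- make_rate_config(seed = 5L, noise_sd = 0, ri = 0, rs = 0,
                          sessions = 1L)
  co <- gen_cohort(cfg)
  truth_at <- eval_shape(cfg$outcome_specs[[1]]$shape,
                         co$data$aligned_age_months)
  expect_equal(co$data$value, truth_at, tolerance = 1e-12)
})

test_that("stored latent truth explains generated data up to configured noise", {
  cfg <- make_rate_config(seed = 21L, noise_sd = 2, ri = 0, rs = 0,
                          sessions = 10L)
  co <- gen_cohort(cfg)
  resid <- co$data$value -
    eval_shape(cfg$outcome_specs[[1]]$shape, co$data$aligned_age_months)
  expect_gte(nrow(co$data), 500L)
  expect_lt(abs(sd(resid) - 2) / 2, 0.2)
})

test_that("binomial session generation matches the binomial oracle", {
  # fixed p = 0.5, n_trials = 200, >= 1000 sessions: mean within 3 SE of 50%
  spec <- outcome_spec("flat_perf", "binomial-performance",
                       logistic_shape(0.5, 0.5, 0, 5), role = "behavior",
                       variant_offsets = c(single = 0), n_trials = 200L,
                       sessions_per_visit = 80L)
  subj <- list(subject_timeline("S01", seq(34, 73, by = 3), 57.9))
  out <- gen_outcome(subj, spec, seed = 77L)
  n_sess <- nrow(out$data)
  expect_gte(n_sess, 1000L)
  se <- 100 * sqrt(0.25 / 200) / sqrt(n_sess)
  expect_lt(abs(mean(out$data$value) - 50), 3 * se)
  expect_true(all(out$data$value >= 0 & out$data$value <= 100))
})

test_that("probabilities pushed outside [0,1] are clamped with a warning", {
  spec <- outcome_spec("sat_perf", "binomial-performance",
                       logistic_shape(0.55, 0.98, -10, 4), role = "behavior",
                       random_intercept_sd = 0.5, sessions_per_visit = 4L)
  subj <- lapply(1:4, function(i)
    subject_timeline(sprintf("S%02d", i), seq(34, 73, by = 3), 57.9))
  expect_warning(out <- gen_outcome(subj, spec, seed = 2L), "clamped")
  expect_gt(out$n_clamped, 0)
  expect_true(all(out$data$value >= 0 & out$data$value <= 100))
})

test_that("tract batteries honour the FA/RD monotonicity sign contract", {
  fa <- tract_battery_specs(53, "FA")
  rd <- tract_battery_specs(53, "RD")
  expect_length(fa, 53L)  # mirrors the 53-tract battery of the study design
  for (s in fa) expect_true(check_shape_monotone(s))
  for (s in rd) expect_true(check_shape_monotone(s))
  grid <- seq(-48, 48, length.out = 501)
  expect_true(all(diff(eval_shape(fa[[10]]$shape, grid)) >= 0))
  expect_true(all(diff(eval_shape(rd[[10]]$shape, grid)) <= 0))
})

test_that("spec constructors reject invalid configurations", {
  expect_error(outcome_spec("bad", "binomial-performance",
                            logistic_shape(-0.2, 0.9, 0, 5),
                            role = "behavior"), "\\[0, 1\\]")
  expect_error(outcome_spec("bad", "gaussian-rate",
                            logistic_shape(1, 2, 0, 5), role = "neural"),
               "noise_sd")
  expect_error(cohort_config(age_start = 70, age_end = 40), "age_start")
  expect_error(logistic_shape(0, 1, 0, scale = 0), "scale")
})
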