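test_that("aligned age is chronological age minus marker age", {
  expect_equal(align_ages(subject_timeline("a", 57.9, 57.9)), 0)
  expect_equal(align_ages(subject_timeline("a", c(34, 69), 58)), c(-24, 11))
  expect_error(align_ages(subject_timeline("a", c(34, 69))), "marker_age")
  expect_error(subject_timeline("a", c(5, 5, 6), 50), "strictly increasing")
  expect_error(subject_timeline("a", 10, marker_age = -1), "> 0")
})

test_that("alignment is a bijection per subject", {
  for (i in 1:20) {
    ages <- sort(runif(8, 30, 80))
    marker <- runif(1, 40, 70)
    tl <- subject_timeline("s", ages, marker)
    expect_equal(align_ages(tl) + marker, ages, tolerance = 1e-12)
  }
  # cohort-level: mean aligned age of the marker event itself is 0
  cfg <- cohort_config(n_subjects = 50L, seed = 2L,
                       outcome_specs = default_outcome_specs(n_tracts = 1))
  subj <- gen_subjects(cfg)
  expect_equal(mean(vapply(subj, function(s)
    s$marker_age - s$marker_age, 1.0)), 0)
})

test_that("align_dataset joins markers and refuses missing ones", {
  d <- data.frame(subject_id = c("a", "a", "b"), age_months = c(40, 50, 60),
                  extra = 1:3)
  m <- data.frame(subject_id = c("a", "b"), marker_age = c(45, 55))
  out <- align_dataset(d, m)
  expect_equal(out$aligned_age_months, c(-5, 5, 5))
  expect_equal(out$extra, 1:3)  # unknown columns preserved
  expect_error(align_dataset(d, m[1, ]), "no marker_age")
})

test_that("session performance is the overall percent of correct trials", {
  expect_equal(session_performance(3, 4), 75)
  expect_equal(session_performance(0, 50), 0)
  expect_error(session_performance(1, 0), "n_trials")
  expect_error(session_performance(5, 4), "n_correct")
  # binomial oracle: 200 sessions at p = 0.8, n = 100
  set.seed(11)
  perf <- session_performance(rbinom(200, 100, 0.8), rep(100, 200))
  expect_true(all(perf >= 0 & perf <= 100))
  expect_lt(abs(mean(perf) - 80), 3 * 100 * sqrt(0.8 * 0.2 / 100) / sqrt(200))
})

test_that("variant pooling combines trials within a session", {
  co <- gen_cohort(cohort_config(seed = 4L, outcome_specs = list(
    outcome_spec("beh", "binomial-performance",
                 logistic_shape(0.5, 0.9, -8, 5), role = "behavior",
                 n_trials = 100L, sessions_per_visit = 2L))))
  raw <- co$data
  pooled <- pool_performance(raw)
  expect_equal(nrow(pooled), nrow(raw) / 3L)       # three variants collapse
  expect_equal(unique(pooled$n_trials), 300L)      # trials sum across variants
  # pooled percent equals total correct over total trials for a spot session
  one <- raw[raw$subject_id == "S01" & raw$age_months == 34 & raw$session == 1, ]
  expect_equal(pooled$value[pooled$subject_id == "S01" &
                              pooled$age_months == 34 & pooled$session == 1],
               100 * sum(one$value * one$n_trials / 100) / sum(one$n_trials))
})

test_that("Mann-Whitney handles separation, identity and tie contracts", {
  sep <- compare_timepoints(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 0)  # complete separation
  same <- compare_timepoints(c(3, 1, 2), c(1, 2, 3))
  expect_gte(same$p.value, 0.99)  # same multiset: no location shift
  expect_equal(compare_timepoints(rep(5, 4), rep(5, 6))$p.value, 1)
  expect_equal(compare_timepoints(rep(2, 20), rep(2, 20))$p.value, 1)
  expect_error(compare_timepoints(numeric(0), 1:3))
})

test_that("exact p-values agree with brute-force enumeration for n <= 7", {
  set.seed(33)
  cases <- list(
    list(g1 = c(1.2, 3.4, 2.2), g2 = c(0.1, 5.5)),
    list(g1 = rnorm(5), g2 = rnorm(7)),
    list(g1 = c(1, 1, 2, 3), g2 = c(1, 2, 2, 4, 4)),   # with ties
    list(g1 = runif(7), g2 = runif(6)),
    list(g1 = c(10, 20), g2 = c(15, 25, 5, 30, 40)))
  for (cs in cases) {
    got <- compare_timepoints(cs$g1, cs$g2)
    expect_equal(got$method, "exact enumeration")
    expect_equal(got$p.value, oracle_mann_whitney(cs$g1, cs$g2),
                 tolerance = 1e-12)
  }
  # tie-free cases also agree with the classical exact test
  for (i in 1:5) {
    g1 <- rnorm(6); g2 <- rnorm(5)
    expect_equal(compare_timepoints(g1, g2)$p.value,
                 wilcox.test(g1, g2, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large well-separated session groups reach the p < 1e-10 regime", {
  set.seed(8)
  young <- rnorm(60, 55, 8)   # first-time-point percent correct
  adult <- rnorm(60, 85, 6)   # adult-stage percent correct
  res <- compare_timepoints(young, adult)
  expect_match(res$method, "normal")
  expect_lt(res$p.value, 1e-10)
  # and the approximation tracks the classical implementation
  expect_equal(res$p.value, wilcox.test(young, adult)$p.value,
               tolerance = 1e-8)
})
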