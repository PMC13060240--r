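test_that("constant data yields a constant curve with zero derivative", {
  d <- make_linear_data(n_subj = 3L, slope = 0, intercept = 7, noise_sd = 0)
  fit <- fit_smooth(d, "lin")
  curve <- predict_grid(fit, n_grid = 100L)
  expect_equal(curve$values, rep(7, 100), tolerance = 1e-8)
  win <- derivative_windows(fit, curve, n_sim = 500L, seed = 1L)
  expect_equal(max(abs(win$derivative)), 0, tolerance = 1e-8)
  expect_equal(nrow(win$intervals), 0L)
})

test_that("noiseless linear data is reproduced exactly on the grid", {
  d <- make_linear_data(n_subj = 2L, slope = 0.8, intercept = 40, noise_sd = 0)
  fit <- fit_smooth(d, "lin", random_effects = FALSE)
  curve <- predict_grid(fit, -24, 15, n_grid = 100L)
  truth <- 40 + 0.8 * curve$grid
  expect_lt(max(abs(curve$values - truth) / abs(truth)), 1e-6)
})

test_that("lambda = 0 without random effects matches the least-squares spline oracle", {
  set.seed(14)
  age <- seq(-24, 15, length.out = 50)
  value <- 60 + 10 * plogis(age / 4) + rnorm(50, 0, 2)
  d <- data.frame(subject_id = "S01", aligned_age_months = age,
                  outcome = "y", value = value)
  fit <- fit_smooth(d, "y", random_effects = FALSE, lambda = 0)
  curve <- predict_grid(fit, -24, 15, n_grid = 100L)
  oracle <- oracle_spline_ols(age, value, curve$grid, k = 5L)
  expect_lt(max(abs(curve$values - oracle) / (abs(oracle) + 1e-8)), 1e-6)
})

test_that("the fixed-lambda smoother is affine equivariant", {
  set.seed(15)
  d <- make_linear_data(n_subj = 3L, slope = 0.5, noise_sd = 3, sessions = 2L)
  base <- predict_grid(fit_smooth(d, "lin", random_effects = FALSE,
                                  lambda = 1), n_grid = 80L)
  d2 <- d; d2$value <- 3 * d$value - 100
  shifted <- predict_grid(fit_smooth(d2, "lin", random_effects = FALSE,
                                     lambda = 1), n_grid = 80L)
  expect_lt(max(abs(shifted$values - (3 * base$values - 100)) /
                  pmax(abs(3 * base$values - 100), 1)), 1e-8)
})

test_that("grid prediction spacing, extremes and extrapolation flags behave", {
  d <- make_linear_data(n_subj = 2L, slope = 1, noise_sd = 0)
  fit <- fit_smooth(d, "lin", random_effects = FALSE)
  curve <- predict_grid(fit, -24, 15, n_grid = 100L)
  expect_length(curve$grid, 100L)
  expect_equal(unique(round(diff(curve$grid), 12)), (15 - (-24)) / 99)
  # monotone increasing fit: extremes at the grid ends
  expect_equal(curve$argmin_age, -24)
  expect_equal(curve$argmax_age, 15)
  expect_true(all(curve$ci_lower <= curve$values &
                    curve$values <= curve$ci_upper))
  # ages beyond the fitted range are permitted but flagged
  expect_warning(ex <- predict_grid(fit, -40, 30, n_grid = 50L),
                 "extrapolate")
  expect_true(any(ex$extrapolated))
  expect_error(predict_grid(fit, 10, 10), "grid_lo")
})

test_that("degenerate designs and unreliable bands are refused", {
  d <- data.frame(subject_id = rep(c("a", "b"), 5),
                  aligned_age_months = rep(3, 10), outcome = "y",
                  value = rnorm(10))
  expect_error(fit_smooth(d, "y"), "rank deficient")
  d2 <- make_linear_data(n_subj = 2L, ages = c(-3, 0, 2, 5))
  expect_error(fit_smooth(d2, "lin"), "distinct aligned ages")
  set.seed(19)
  d3 <- make_linear_data(noise_sd = 1)
  fit <- suppressWarnings(fit_smooth(d3, "lin"))
  expect_error(derivative_windows(fit, predict_grid(fit), n_sim = 50L),
               "n_sim")
  expect_error(fit_smooth(d3, "nope"), "no rows")
})

test_that("derivative windows detect a linear trend with the right sign", {
  set.seed(16)
  d <- make_linear_data(n_subj = 4L, slope = 0.5, noise_sd = 1, sessions = 3L)
  fit <- fit_smooth(d, "lin")
  curve <- predict_grid(fit, n_grid = 100L)
  win <- derivative_windows(fit, curve, n_sim = 2000L, seed = 2L)
  expect_gte(mean(win$flagged == 1L), 0.9)
  expect_true(all(win$flagged >= 0L))
  # flagged sign always agrees with the numerical slope of the fitted curve
  slope_sign <- sign(diff(curve$values))
  inner <- which(win$flagged != 0L & seq_along(win$flagged) < 100L)
  expect_true(all(win$flagged[inner] == slope_sign[inner]))
  # intervals are disjoint and inside the grid
  if (nrow(win$intervals) > 1L)
    expect_true(all(win$intervals$start[-1] > head(win$intervals$end, -1)))
  expect_true(all(win$intervals$start >= curve$grid[1] &
                    win$intervals$end <= curve$grid[100]))
})

test_that("pointwise intervals achieve near-nominal coverage on a smooth truth", {
  # repeated draws around a fixed smooth truth; average pointwise coverage
  ages <- seq(-24, 15, length.out = 60)
  truth_fun <- function(a) 50 + 20 * plogis((a + 5) / 6)
  covered <- 0; total <- 0
  for (rep in 1:200) {
    set.seed(300 + rep)
    d <- data.frame(subject_id = "S01", aligned_age_months = ages,
                    outcome = "y", value = truth_fun(ages) + rnorm(60, 0, 2))
    curve <- predict_grid(fit_smooth(d, "y", random_effects = FALSE),
                          -24, 15, n_grid = 50L)
    tr <- truth_fun(curve$grid)
    covered <- covered + sum(curve$ci_lower <= tr & tr <= curve$ci_upper)
    total <- total + 50
  }
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.995)
})

test_that("BH adjustment matches closed forms and the step-up oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)          # m = 1 identity
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in p
  }
})
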