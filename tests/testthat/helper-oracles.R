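# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately recompute quantities by a different route than the
# package implementation.

# Brute-force two-sided Mann-Whitney p over all group assignments; the U
# statistic is computed by direct pairwise comparison (not via ranks).
oracle_mann_whitney <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1); N <- length(pooled)
  u_pairwise <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_pairwise(g1, g2)
  mu <- n1 * (N - n1) / 2
  us <- combn(N, n1, function(idx) u_pairwise(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Step-up BH adjustment written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  pmin(adj, 1)
}

# Unpenalized least-squares fit on the cubic shrinkage spline basis,
# predicted on a grid: the lambda -> 0, no-random-effects oracle.
oracle_spline_ols <- function(age, value, grid, k = 5L) {
  sm <- mgcv::smoothCon(mgcv::s(age, k = k, bs = "cs"),
                        data = data.frame(age = age),
                        absorb.cons = TRUE)[[1]]
  X <- cbind(1, sm$X)
  beta <- qr.solve(X, value)
  Xg <- cbind(1, mgcv::PredictMat(sm, data.frame(age = grid)))
  drop(Xg %*% beta)
}

# Long-format data frame from per-subject straight lines plus optional noise.
make_linear_data <- function(n_subj = 3L, ages = seq(-24, 15, by = 3),
                             intercept = 50, slope = 0.5, noise_sd = 0,
                             sessions = 1L, outcome = "lin") {
  rows <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subj)),
                      aligned_age_months = ages, session = seq_len(sessions),
                      stringsAsFactors = FALSE)
  rows$value <- intercept + slope * rows$aligned_age_months +
    rnorm(nrow(rows), 0, noise_sd)
  rows$outcome <- outcome
  rows
}

# Minimal gaussian-rate cohort: one outcome, tweakable shape/noise.
make_rate_config <- function(seed, shape = logistic_shape(12, 32, 0, 8),
                             noise_sd = 1, ri = 0.5, rs = 0.01,
                             sessions = 19L) {
  cohort_config(seed = seed, outcome_specs = list(
    outcome_spec("pfc_rate", "gaussian-rate", shape, role = "neural",
                 noise_sd = noise_sd, random_intercept_sd = ri,
                 random_slope_sd = rs, sessions_per_visit = sessions)))
}
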