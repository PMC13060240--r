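#' Fit a penalized-spline mixed model for one outcome
#'
#' Fits, per outcome, a Gaussian additive mixed model of value on aligned age:
#' a cubic regression spline with shrinkage penalty (`bs = "cs"`, `k` basis
#' functions — with infinite smoothing the smooth shrinks to zero rather than
#' to an unpenalized line) plus subject-specific random intercepts and random
#' slopes on aligned age, estimated by REML. Session percent-correct is
#' modelled on the percent scale (the session-level metric the trajectories
#' are drawn for), a deliberate Gaussian modelling choice.
#'
#' Only complete cases of (subject, aligned age, value) are used. If the full
#' random-effects model fails, the fit falls back to random intercepts only,
#' then to no random effects, each with a warning.
#'
#' @param data long-format data frame with columns `subject_id`,
#'   `aligned_age_months`, `outcome`, `value`.
#' @param outcome outcome label to fit (must be present in `data$outcome`).
#' @param k spline basis dimension (default 5).
#' @param random_effects include subject random intercept + slope terms
#'   (default `TRUE`). With `FALSE` the model is a pure penalized spline.
#' @param lambda optional fixed smoothing parameter for the age smooth;
#'   `lambda = 0` gives the unpenalized regression-spline fit. `NULL`
#'   (default) selects lambda by REML.
#' @return an object of class `smooth_fit`: the fitted \pkg{mgcv} model plus
#'   `outcome`, `k`, `lambda`, `beta`, `V_beta`, `scale` (residual variance),
#'   `random_effects` (per-subject intercept/slope estimates, if any),
#'   `p_smooth` (Wald-type p-value of the age smooth), `n_obs`, `age_range`.
#' @export
fit_smooth <- function(data, outcome, k = 5L, random_effects = TRUE,
                       lambda = NULL) {
  stopifnot(all(c("subject_id", "aligned_age_months", "outcome", "value")
                %in% names(data)))
  df <- data[data$outcome == outcome,
             c("subject_id", "aligned_age_months", "value")]
  if (nrow(df) == 0L) stop(sprintf("no rows for outcome '%s'", outcome),
                           call. = FALSE)
  df <- df[complete.cases(df), ]
  df <- data.frame(subject = factor(df$subject_id),
                   age = df$aligned_age_months, value = df$value)
  n_distinct_age <- length(unique(df$age))
  if (n_distinct_age < 2L)
    stop("design is rank deficient: all aligned ages are equal", call. = FALSE)
  if (n_distinct_age < k + 2L)
    stop(sprintf("need >= %d distinct aligned ages for k = %d", k + 2L, k),
         call. = FALSE)
  if (random_effects && nlevels(df$subject) < 2L)
    stop("random effects require >= 2 subjects", call. = FALSE)

  # a zero-variance response carries no trajectory information: represent
  # the degenerate intercept-only fit directly (constant curve, zero
  # derivative, zero coefficient uncertainty)
  if (sd(df$value) == 0) {
    return(structure(list(model = NULL, outcome = outcome,
                          k = as.integer(k), lambda = Inf,
                          beta = c(`(Intercept)` = df$value[1]),
                          V_beta = matrix(0, 1, 1),
                          scale = 0, random_effects = NULL,
                          p_smooth = 1, n_obs = nrow(df),
                          age_range = range(df$age),
                          subjects = levels(df$subject)),
                     class = "smooth_fit"))
  }

  age_sm <- if (is.null(lambda)) sprintf("s(age, k = %d, bs = \"cs\")", k)
            else sprintf("s(age, k = %d, bs = \"cs\", sp = %.17g)", k, lambda)
  forms <- if (random_effects) c(
    paste("value ~", age_sm,
          "+ s(subject, bs = \"re\") + s(age, subject, bs = \"re\")"),
    paste("value ~", age_sm, "+ s(subject, bs = \"re\")"),
    paste("value ~", age_sm)
  ) else paste("value ~", age_sm)

  model <- NULL
  for (i in seq_along(forms)) {
    model <- tryCatch(
      mgcv::gam(stats::as.formula(forms[i]), data = df, method = "REML"),
      error = function(e) NULL)
    if (!is.null(model)) {
      if (i > 1L)
        warning(sprintf(
          "outcome '%s': random-effect structure simplified to '%s'",
          outcome, forms[i]), call. = FALSE)
      break
    }
  }
  if (is.null(model))
    stop(sprintf("REML fit failed for outcome '%s'", outcome), call. = FALSE)

  smr <- summary(model)
  p_smooth <- unname(smr$s.table[grep("^s\\(age\\)", rownames(smr$s.table)),
                                 "p-value"][1])
  re <- NULL
  if (random_effects && length(model$smooth) > 1L) {
    cf <- coef(model)
    re <- lapply(model$smooth[-1L], function(sm)
      setNames(cf[sm$first.para:sm$last.para], levels(df$subject)))
    names(re) <- vapply(model$smooth[-1L], `[[`, "", "label")
  }
  structure(list(model = model, outcome = outcome, k = as.integer(k),
                 lambda = unname(model$sp[1]), beta = coef(model),
                 V_beta = model$Vp, scale = model$sig2,
                 random_effects = re, p_smooth = p_smooth,
                 n_obs = nrow(df), age_range = range(df$age),
                 subjects = levels(df$subject)),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat(sprintf("smooth_fit '%s': k = %d, lambda = %.4g, n = %d, scale = %.4g\n",
              x$outcome, x$k, x$lambda, x$n_obs, x$scale))
  cat(sprintf("  aligned-age range [%.1f, %.1f] months; smooth p = %.3g\n",
              x$age_range[1], x$age_range[2], x$p_smooth))
  invisible(x)
}

# Population-level linear predictor matrix at given aligned ages:
# the lpmatrix with subject random-effect columns zeroed out.
population_lpmatrix <- function(fit, age) {
  if (is.null(fit$model))  # degenerate constant fit: intercept column only
    return(matrix(1, length(age), 1))
  nd <- data.frame(age = age, subject = factor(fit$subjects[1],
                                               levels = fit$subjects))
  Xp <- predict(fit$model, newdata = nd, type = "lpmatrix")
  for (sm in fit$model$smooth)
    if (grepl("subject", sm$label, fixed = TRUE))
      Xp[, sm$first.para:sm$last.para] <- 0
  Xp
}

#' Predict the population trajectory on a fixed maturation grid
#'
#' Evaluates the fitted population curve (random effects set to zero) on
#' `n_grid` evenly spaced aligned ages from `grid_lo` to `grid_hi` inclusive,
#' with pointwise Wald confidence intervals from the coefficient covariance,
#' and records the grid locations of the fitted minimum and maximum.
#' Extrapolation beyond the fitted age range is permitted but flagged.
#'
#' @param fit a [fit_smooth()] result.
#' @param grid_lo,grid_hi grid bounds (aligned months); default to the fitted
#'   data range. In a similarity family the bounds are conventionally taken
#'   from the behavioral data's earliest and latest aligned ages.
#' @param n_grid number of grid points (default 100).
#' @param level pointwise confidence level (default 0.95).
#' @return an object of class `trajectory_curve`: `grid`, `values`,
#'   `ci_lower`, `ci_upper`, `se`, `argmin_age`, `argmax_age`, `extrapolated`
#'   (logical per grid point), `outcome`.
#' @export
predict_grid <- function(fit, grid_lo = NULL, grid_hi = NULL, n_grid = 100L,
                         level = 0.95) {
  stopifnot(inherits(fit, "smooth_fit"))
  if (is.null(grid_lo)) grid_lo <- fit$age_range[1]
  if (is.null(grid_hi)) grid_hi <- fit$age_range[2]
  if (!(grid_lo < grid_hi)) stop("grid_lo must be < grid_hi", call. = FALSE)
  assert_scalar_num(n_grid, "n_grid", lower = 2)
  grid <- seq(grid_lo, grid_hi, length.out = n_grid)
  Xp <- population_lpmatrix(fit, grid)
  mu <- drop(Xp %*% fit$beta)
  se <- sqrt(pmax(rowSums((Xp %*% fit$V_beta) * Xp), 0))
  zc <- qnorm(1 - (1 - level) / 2)
  extrap <- grid < fit$age_range[1] - 1e-9 | grid > fit$age_range[2] + 1e-9
  if (any(extrap))
    warning(sprintf("outcome '%s': %d of %d grid points extrapolate beyond the fitted age range",
                    fit$outcome, sum(extrap), n_grid), call. = FALSE)
  structure(list(outcome = fit$outcome, grid = grid, values = mu,
                 ci_lower = mu - zc * se, ci_upper = mu + zc * se, se = se,
                 argmin_age = grid[which.min(mu)],
                 argmax_age = grid[which.max(mu)],
                 level = level, extrapolated = extrap),
            class = "trajectory_curve")
}

#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("trajectory_curve '%s': %d points on [%.2f, %.2f] months\n",
              x$outcome, length(x$grid), x$grid[1], x$grid[length(x$grid)]))
  cat(sprintf("  min %.4g at %.2f mo; max %.4g at %.2f mo\n",
              min(x$values), x$argmin_age, max(x$values), x$argmax_age))
  invisible(x)
}

#' Significant developmental-change windows from derivative bands
#'
#' Approximates the derivative of the fitted population curve at each grid
#' point by central finite differences (step = the grid spacing) and builds a
#' simultaneous `1 - alpha` confidence band by posterior simulation: `n_sim`
#' coefficient draws from Normal(beta, V_beta), critical value the
#' `1 - alpha` quantile of the maximum absolute standardized deviation across
#' the grid. Contiguous grid runs where the band excludes zero become change
#' windows, signed by the derivative's direction.
#'
#' @param fit a [fit_smooth()] result.
#' @param curve the [predict_grid()] curve whose grid defines the evaluation
#'   points and finite-difference step.
#' @param n_sim posterior draws (>= 100; default 10000).
#' @param alpha simultaneous level (default 0.05).
#' @param seed optional integer seed for the posterior draws.
#' @return an object of class `change_windows`: `intervals` (tibble with
#'   `start`, `end`, `sign`), `derivative`, `se`, `flagged` (signed integer
#'   per grid point), `crit`, `alpha`, `grid`, `outcome`.
#' @export
derivative_windows <- function(fit, curve, n_sim = 10000L, alpha = 0.05,
                               seed = NULL) {
  stopifnot(inherits(fit, "smooth_fit"), inherits(curve, "trajectory_curve"))
  if (n_sim < 100L) stop("n_sim must be >= 100 for a reliable band",
                         call. = FALSE)
  assert_scalar_num(alpha, "alpha", lower = 1e-6, upper = 0.5)
  grid <- curve$grid
  h <- grid[2] - grid[1]
  Xd <- (population_lpmatrix(fit, grid + h) -
         population_lpmatrix(fit, grid - h)) / (2 * h)
  d <- drop(Xd %*% fit$beta)
  se <- sqrt(pmax(rowSums((Xd %*% fit$V_beta) * Xd), 0))
  ok <- se > 1e-12
  flagged <- integer(length(grid))
  crit <- NA_real_
  if (any(ok)) {
    dev <- with_seed(seed, {
      B <- MASS::mvrnorm(n_sim, mu = rep(0, length(fit$beta)),
                         Sigma = fit$V_beta, tol = 1e-8)
      Xd[ok, , drop = FALSE] %*% t(B)
    })
    maxstat <- apply(abs(dev) / se[ok], 2, max)
    crit <- quantile(maxstat, 1 - alpha, names = FALSE)
    lo <- d - crit * se
    hi <- d + crit * se
    flagged[ok & lo > 0] <- 1L
    flagged[ok & hi < 0] <- -1L
  }
  runs <- rle(flagged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != 0L
  intervals <- tibble(start = grid[starts[keep]], end = grid[ends[keep]],
                      sign = runs$values[keep])
  structure(list(outcome = fit$outcome, intervals = intervals,
                 derivative = d, se = se, flagged = flagged, crit = crit,
                 alpha = alpha, grid = grid),
            class = "change_windows")
}

#' @export
print.change_windows <- function(x, ...) {
  cat(sprintf("change_windows '%s' (simultaneous %g%% band):\n",
              x$outcome, 100 * (1 - x$alpha)))
  if (nrow(x$intervals) == 0L) cat("  no significant developmental windows\n")
  else for (i in seq_len(nrow(x$intervals)))
    cat(sprintf("  [%.2f, %.2f] months, %s\n", x$intervals$start[i],
                x$intervals$end[i],
                if (x$intervals$sign[i] > 0) "increasing" else "decreasing"))
  invisible(x)
}

#' Benjamini–Hochberg false discovery rate adjustment
#'
#' Standard BH step-up adjusted p-values (monotone, capped at 1), applied
#' across the per-outcome tests of the age smooth when several outcomes are
#' modelled in separate fits.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]; may be empty.
#' @return adjusted p-values, same length and names.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03))
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(is.numeric(pvals))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}
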