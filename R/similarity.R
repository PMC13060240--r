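#' z-score a trajectory curve
#'
#' Centers and scales to sample mean 0 and sample SD 1 (divisor n − 1). The
#' similarity statistics are defined on z-scored curves so that affine
#' transforms of either raw trajectory (positive scale) leave them unchanged.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return z-scored vector.
#' @examples
#' zscore_curve(c(0, 1, 2))
#' @export
zscore_curve <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L, !anyNA(values))
  s <- sd(values)
  if (s <= 0)
    stop("curve is constant: trajectory similarity is undefined for flat curves",
         call. = FALSE)
  (values - mean(values)) / s
}

#' Baseline-shift and fold a z-scored curve
#'
#' Shifts the curve so its starting point is zero (subtracting the first
#' value) and then takes absolute values, folding rising and falling curves
#' onto a common non-negative scale so RMSE compares positively and
#' negatively correlated trajectory pairs alike.
#'
#' @param z numeric vector (typically z-scored), length >= 2.
#' @return non-negative vector with first element 0.
#' @examples
#' shift_abs(c(2, 1, 0))  # folds onto c(0, 1, 2)
#' @export
shift_abs <- function(z) {
  stopifnot(is.numeric(z), length(z) >= 2L, !anyNA(z))
  abs(z - z[1])
}

#' RMSE between folded trajectory curves
#'
#' `sqrt(mean((X_i - Y_i)^2))` over the baseline-shifted absolute (folded)
#' curves; symmetric in its arguments and zero iff the folded curves coincide.
#'
#' @param x_folded,y_folded folded curves of equal length (>= 2), from
#'   [shift_abs()].
#' @return non-negative scalar.
#' @examples
#' trajectory_rmse(c(0, 1, 2), c(0, 0, 0))  # sqrt(5/3)
#' @export
trajectory_rmse <- function(x_folded, y_folded) {
  stopifnot(is.numeric(x_folded), is.numeric(y_folded),
            length(x_folded) >= 2L)
  if (length(x_folded) != length(y_folded))
    stop("folded curves must have equal length", call. = FALSE)
  sqrt(mean((x_folded - y_folded)^2))
}

#' Pearson correlation between trajectory curves
#'
#' @param x_z,y_z curves of equal length sharing a grid; z-scoring does not
#'   change the result (Pearson r is affine invariant) but for z-scored
#'   inputs r equals `sum(x_z * y_z) / (n - 1)`.
#' @return Pearson r in \[-1, 1\].
#' @export
trajectory_corr <- function(x_z, y_z) {
  stopifnot(is.numeric(x_z), is.numeric(y_z), length(x_z) >= 2L)
  if (length(x_z) != length(y_z))
    stop("curves must have equal length", call. = FALSE)
  cor(x_z, y_z)
}

#' maxT permutation p-values for a family of curve pairs
#'
#' For each of `n_perm` permutations, every pair's Y curve has its grid
#' indices independently randomly permuted and the Pearson correlation is
#' recomputed; the null statistic `T_b` is the maximum of |r| over the family.
#' The family-wise adjusted p-value of a pair is
#' `(1 + #\{b : T_b >= |r_obs|\}) / (n_perm + 1)`, so the smallest achievable
#' value is `1 / (n_perm + 1)`. A single pair degenerates to an unadjusted
#' permutation test.
#'
#' Note: permuting grid indices treats grid points as exchangeable under the
#' null. Smooth fitted curves are strongly autocorrelated, so this null is
#' anti-conservative for smooth trajectories — p-values should be read as a
#' family-wise-calibrated ranking device, as in the source analysis, not as
#' exact error rates.
#'
#' @param pairs list of pairs, each a list with two numeric elements `x` and
#'   `y` of common length across the family (the shared grid).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed optional integer seed; results are deterministic under it.
#' @return tibble with one row per pair: `pair`, `r`, `p_perm` (unadjusted
#'   permutation p), `p_maxT`.
#' @export
maxt_permutation <- function(pairs, n_perm = 1000L, seed = NULL) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  xs <- lapply(pairs, function(p) zscore_curve(p$x))
  ys <- lapply(pairs, function(p) zscore_curve(p$y))
  n <- unique(c(vapply(xs, length, 1L), vapply(ys, length, 1L)))
  if (length(n) != 1L)
    stop("all pairs must share one grid length", call. = FALSE)
  m <- length(pairs)
  r_obs <- vapply(seq_len(m), function(i) trajectory_corr(xs[[i]], ys[[i]]),
                  1.0)
  r_perm <- with_seed(seed, {
    vapply(seq_len(m), function(i) {
      perms <- vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
      drop(crossprod(ys[[i]][perms] |> matrix(nrow = n), xs[[i]])) / (n - 1)
    }, numeric(n_perm))
  })
  r_perm <- matrix(r_perm, nrow = n_perm, ncol = m)
  t_max <- apply(abs(r_perm), 1, max)
  eps <- 1e-12
  p_maxT <- vapply(abs(r_obs), function(r0)
    (1 + sum(t_max >= r0 - eps)) / (n_perm + 1), 1.0)
  p_perm <- vapply(seq_len(m), function(i)
    (1 + sum(abs(r_perm[, i]) >= abs(r_obs[i]) - eps)) / (n_perm + 1), 1.0)
  nm <- names(pairs)
  if (is.null(nm)) nm <- sprintf("pair_%02d", seq_len(m))
  tibble(pair = nm, r = r_obs, p_perm = p_perm, p_maxT = p_maxT)
}

#' Similarity of a family of curves against a reference trajectory
#'
#' Computes, for each target curve against the shared reference (typically
#' pooled behavioral performance): Pearson r of the z-scored curves, RMSE of
#' the folded (baseline-shifted absolute) curves, and maxT permutation
#' p-values with the family defined as all targets in this call.
#'
#' @param reference numeric vector or [predict_grid()] curve.
#' @param targets named list of numeric vectors or `trajectory_curve`s on the
#'   same grid.
#' @param n_perm,seed passed to [maxt_permutation()].
#' @return tibble: `pair`, `r`, `rmse`, `p_perm`, `p_maxT`.
#' @export
curve_similarity <- function(reference, targets, n_perm = 1000L, seed = NULL) {
  vals <- function(x) if (inherits(x, "trajectory_curve")) x$values else x
  ref <- vals(reference)
  stopifnot(is.list(targets), length(targets) >= 1L)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("targets must be a named list", call. = FALSE)
  ref_z <- zscore_curve(ref)
  ref_f <- shift_abs(ref_z)
  pairs <- lapply(targets, function(y) list(x = ref, y = vals(y)))
  out <- maxt_permutation(pairs, n_perm = n_perm, seed = seed)
  out$rmse <- vapply(targets, function(y)
    trajectory_rmse(ref_f, shift_abs(zscore_curve(vals(y)))), 1.0)
  out[, c("pair", "r", "rmse", "p_perm", "p_maxT")]
}

#' Summarize a family of similarity results
#'
#' Medians of |r| and RMSE over the family, plus the per-pair table sorted by
#' |r| descending (the "highest-alignment tracts first" presentation).
#'
#' @param results tibble from [curve_similarity()] (columns `pair`, `r`,
#'   `rmse`, and optionally p-values).
#' @return list: `median_abs_r`, `median_r`, `median_rmse`, `table`.
#' @export
family_summary <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L,
            all(c("pair", "r", "rmse") %in% names(results)))
  list(median_abs_r = median(abs(results$r)),
       median_r = median(results$r),
       median_rmse = median(results$rmse),
       table = results[order(-abs(results$r)), ])
}
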