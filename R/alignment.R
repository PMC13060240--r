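#' A subject's observation timeline and maturation marker
#'
#' @param subject_id subject label.
#' @param visit_ages strictly increasing chronological visit ages (months).
#' @param marker_age maturation-marker age (months, > 0) — e.g. the age at
#'   distal tibial epiphyseal closure, used as the mid-adolescence anchor.
#' @return an object of class `subject_timeline`.
#' @export
subject_timeline <- function(subject_id, visit_ages, marker_age = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            is.numeric(visit_ages), length(visit_ages) >= 1L)
  if (any(diff(visit_ages) <= 0))
    stop("visit_ages must be strictly increasing", call. = FALSE)
  if (!is.null(marker_age)) {
    assert_scalar_num(marker_age, "marker_age")
    if (marker_age <= 0) stop("marker_age must be > 0", call. = FALSE)
  }
  structure(list(subject_id = subject_id, visit_ages = as.numeric(visit_ages),
                 marker_age = marker_age), class = "subject_timeline")
}

#' Align chronological ages to the maturation marker
#'
#' Aligned age is chronological age minus the subject's maturation-marker age,
#' so zero corresponds to the marker event (mid-adolescence). No imputation is
#' performed: a missing marker is an error.
#'
#' @param timeline a [subject_timeline()] with `marker_age` set.
#' @return numeric vector of aligned ages (months), one per visit.
#' @examples
#' align_ages(subject_timeline("S01", c(34, 69), marker_age = 58))
#' @export
align_ages <- function(timeline) {
  stopifnot(inherits(timeline, "subject_timeline"))
  if (is.null(timeline$marker_age) || is.na(timeline$marker_age))
    stop(sprintf("subject '%s' has no marker_age; alignment requires one",
                 timeline$subject_id), call. = FALSE)
  timeline$visit_ages - timeline$marker_age
}

#' Align a long-format dataset against a marker table
#'
#' Adds/overwrites `aligned_age_months = age_months - marker_age` by subject.
#' Unknown columns are preserved untouched.
#'
#' @param data data frame with columns `subject_id` and `age_months`.
#' @param markers data frame with columns `subject_id` and `marker_age`.
#' @return `data` with an `aligned_age_months` column.
#' @export
align_dataset <- function(data, markers) {
  stopifnot(all(c("subject_id", "age_months") %in% names(data)),
            all(c("subject_id", "marker_age") %in% names(markers)))
  idx <- match(data$subject_id, markers$subject_id)
  if (anyNA(idx)) {
    miss <- unique(data$subject_id[is.na(idx)])
    stop("no marker_age for subject(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- markers$marker_age[idx]
  if (anyNA(m) || any(m <= 0))
    stop("marker_age must be present and > 0 for every subject", call. = FALSE)
  data$aligned_age_months <- data$age_months - m
  data
}

#' Session percent-correct
#'
#' Performance is the overall percentage of trials in a session with a correct
#' response, `100 * n_correct / n_trials`.
#'
#' @param n_correct,n_trials trial counts (vectorized); requires
#'   `0 <= n_correct <= n_trials` and `n_trials > 0`.
#' @return percent in \[0, 100\].
#' @examples
#' session_performance(3, 4)  # 75
#' @export
session_performance <- function(n_correct, n_trials) {
  stopifnot(is.numeric(n_correct), is.numeric(n_trials),
            length(n_correct) == length(n_trials))
  if (any(n_trials <= 0)) stop("n_trials must be > 0", call. = FALSE)
  if (any(n_correct < 0 | n_correct > n_trials))
    stop("need 0 <= n_correct <= n_trials", call. = FALSE)
  100 * n_correct / n_trials
}

#' Pool session performance across task variants
#'
#' Collapses per-variant rows of a binomial-performance outcome to one
#' percent-correct per (subject, visit, session) over all variants' trials
#' combined. Used to build the pooled behavioral reference trajectory, since
#' per-variant trajectories are nearly perfectly correlated.
#'
#' @param data long-format rows of one binomial outcome (columns `subject_id`,
#'   `age_months`, `aligned_age_months`, `session`, `value`, `n_trials`).
#' @param name outcome label for the pooled rows.
#' @return tibble in the same long schema with `variant = "pooled"`.
#' @export
pool_performance <- function(data, name = "behavior_pooled") {
  need <- c("subject_id", "age_months", "aligned_age_months", "session",
            "value", "n_trials")
  stopifnot(all(need %in% names(data)))
  if (any(is.na(data$n_trials))) stop("n_trials required for pooling",
                                      call. = FALSE)
  n_corr <- data$value * data$n_trials / 100
  key <- interaction(data$subject_id, data$age_months, data$session,
                     drop = TRUE)
  agg <- function(x) as.numeric(tapply(x, key, sum))
  first <- function(x) tapply(x, key, `[`, 1)
  out <- tibble(
    subject_id = as.character(first(data$subject_id)),
    age_months = as.numeric(first(data$age_months)),
    aligned_age_months = as.numeric(first(data$aligned_age_months)),
    outcome = name, variant = "pooled",
    session = as.integer(first(data$session)),
    value = session_performance(agg(n_corr), agg(data$n_trials)),
    n_trials = as.integer(agg(data$n_trials)))
  out[order(out$subject_id, out$age_months, out$session), ]
}

#' Mann–Whitney U comparison of two session-performance groups
#'
#' Two-sided Mann–Whitney U test. For combined sample size at most 16 the
#' null distribution of U is enumerated exactly over all group assignments
#' (handling ties by construction); for larger samples a tie-corrected normal
#' approximation with continuity correction is used. When every value is
#' identical across both groups the p-value is 1 by contract.
#'
#' @param group1,group2 non-empty numeric vectors (e.g. percent-correct).
#' @param exact_max_n combined-size threshold below/at which enumeration
#'   is used.
#' @return list with `statistic` (U for `group1`), `p.value`, and `method`.
#' @examples
#' compare_timepoints(c(1, 2), c(3, 4))$statistic  # complete separation: U = 0
#' @export
compare_timepoints <- function(group1, group2, exact_max_n = 16L) {
  stopifnot(is.numeric(group1), is.numeric(group2),
            length(group1) >= 1L, length(group2) >= 1L,
            !anyNA(group1), !anyNA(group2))
  n1 <- length(group1); n2 <- length(group2); N <- n1 + n2
  pooled <- c(group1, group2)
  u_of <- function(idx1) {  # U for the group formed by pooled[idx1]
    r <- rank(pooled)
    sum(r[idx1]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= exact_max_n) {
    us <- combn(N, n1, u_of)
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = u_obs, p.value = p, method = method)
}
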