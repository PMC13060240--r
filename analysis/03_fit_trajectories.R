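#!/usr/bin/env Rscript
# Stage 3 — penalized-spline mixed-model trajectories.
#
# Fits, for every outcome, a cubic shrinkage-spline (k = 5) mixed model of
# value on aligned age with subject random intercepts and slopes (REML),
# applies Benjamini-Hochberg correction to the per-outcome smooth tests,
# predicts every trajectory on the shared 100-point maturation grid bounded
# by the behavioral data, and extracts significant developmental-change
# windows from finite-difference derivatives with simultaneous 95% bands.
# Writes fits.csv, curves.csv and windows.csv under results/trajectories/.

library(trajalign)

seed <- as.integer(Sys.getenv("TRAJALIGN_SEED", "1"))
data <- read_long_data("results/cohort/data.csv")

pooled <- pool_performance(data[data$outcome == "antisaccade", ])
analysis_data <- rbind(data[data$outcome != "antisaccade", ], pooled)
outcomes <- c("behavior_pooled",
              setdiff(unique(data$outcome), "antisaccade"))

message(sprintf("fitting %d outcomes (k = 5, REML)", length(outcomes)))
fits <- lapply(outcomes, function(nm) fit_smooth(analysis_data, nm))
names(fits) <- outcomes
p_fdr <- fdr_adjust(vapply(fits, `[[`, 1.0, "p_smooth"))

glo <- min(pooled$aligned_age_months)
ghi <- max(pooled$aligned_age_months)
message(sprintf("behavior-defined grid: [%.1f, %.1f] aligned months",
                glo, ghi))
curves <- lapply(fits, predict_grid, grid_lo = glo, grid_hi = ghi)

sig <- outcomes[p_fdr < 0.05]
message(sprintf("%d / %d outcomes significant after FDR; extracting windows",
                length(sig), length(outcomes)))
windows <- lapply(sig, function(nm)
  derivative_windows(fits[[nm]], curves[[nm]],
                     seed = as.integer((seed * 131 + match(nm, outcomes))
                                       %% .Machine$integer.max)))

dir.create("results/trajectories", showWarnings = FALSE, recursive = TRUE)
write.csv(data.frame(
  outcome = outcomes,
  lambda = vapply(fits, `[[`, 1.0, "lambda"),
  scale = vapply(fits, `[[`, 1.0, "scale"),
  argmin_age = vapply(curves, `[[`, 1.0, "argmin_age"),
  argmax_age = vapply(curves, `[[`, 1.0, "argmax_age"),
  p_smooth = vapply(fits, `[[`, 1.0, "p_smooth"), p_fdr = p_fdr),
  "results/trajectories/fits.csv", row.names = FALSE)
write.csv(do.call(rbind, lapply(curves, function(cv)
  data.frame(outcome = cv$outcome, aligned_age_months = cv$grid,
             value = cv$values, ci_lower = cv$ci_lower,
             ci_upper = cv$ci_upper))),
  "results/trajectories/curves.csv", row.names = FALSE)
win_df <- do.call(rbind, lapply(windows, function(w)
  if (nrow(w$intervals)) data.frame(outcome = w$outcome, w$intervals)))
if (is.null(win_df)) win_df <- data.frame(outcome = character(),
                                          start = numeric(), end = numeric(),
                                          sign = integer())
write.csv(win_df, "results/trajectories/windows.csv", row.names = FALSE)

beh_win <- win_df[win_df$outcome == "behavior_pooled", ]
if (nrow(beh_win))
  message(sprintf(
    "behavior improves significantly on [%.1f, %.1f] aligned months",
    beh_win$start[1], beh_win$end[nrow(beh_win)]))
message("wrote results/trajectories/{fits,curves,windows}.csv")
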