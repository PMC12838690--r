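#!/usr/bin/env Rscript
# One-off tuning of the fixed PID fuzzy-hybrid baseline on the
# habituation-free plant.  The gains found here (Kp = 0.8, Ki = 0.05,
# Kd = 0.2 on the normalized bearing error) are frozen into pid_fuzzy();
# the script is shipped for transparency and is not part of the test run.
#
# Usage: Rscript scripts/tune_pid.R [--seeds <n>]

suppressPackageStartupMessages(library(anfishab))

args <- commandArgs(trailingOnly = TRUE)
n_seeds <- if (length(i <- which(args == "--seeds")) && i < length(args))
  as.integer(args[i + 1]) else 5L

hp <- hab_params(I_s0 = 0, I_l = 0, sigma_s = 0, sigma_l = 0)
profile <- specimen_profile(hab = hp)
ar <- arena()

grid <- expand.grid(Kp = c(0.4, 0.8, 1.2), Ki = c(0, 0.05, 0.1),
                    Kd = c(0, 0.2, 0.4))
best <- NULL
for (g in seq_len(nrow(grid))) {
  maes <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sp <- sample_specimen(profile, 0.45, seed = 7000L + s)
    pid <- pid_fuzzy(Kp = grid$Kp[g], Ki = grid$Ki[g], Kd = grid$Kd[g],
                     ibi_fixed = 0.2)
    tel <- run_trial(pid, sp, ar, duration = 120, dt = 0.1, seed = s)
    maes[s] <- navigation_metrics(tel, sp)$mae_deg
  }
  score <- mean(maes)
  cat(sprintf("Kp=%.1f Ki=%.2f Kd=%.1f  mean MAE=%.1f deg\n",
              grid$Kp[g], grid$Ki[g], grid$Kd[g], score))
  if (is.null(best) || score < best$score)
    best <- list(score = score, row = grid[g, ])
}
cat("best: "); print(best$row)
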