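#!/usr/bin/env Rscript
# First-level GLM demonstration on simulated BOLD runs: builds the design
# (16 s mini-block boxcars + 4 s rinse convolved with the canonical HRF,
# six motion parameters, spike regressors for frames with framewise
# displacement > 1 mm, 128 s discrete-cosine high-pass, run intercept),
# fits OLS run-wise betas, and checks recovery of the planted amplitudes.

library(flavdecode)

seed <- as.integer(commandArgs(TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/firstlevel", recursive = TRUE, showWarnings = FALSE)

pat <- simulate_patterns(synth_config(grid = c(10L, 10L, 8L)), seed = seed)
rows <- list()
for (run in 1:3) {
  sched <- make_design_events(seed = seed + run, run_id = run)
  bold <- simulate_timeseries(sched, pat,
                              ts_config(noise_sd = 1, motion_sd = 0.02),
                              seed = seed + 100L + run)
  fl <- run_first_level(bold, sched)
  planted <- t(bold$amplitudes)[rownames(fl$betas), , drop = FALSE]
  rows[[run]] <- data.frame(
    run = run,
    censored_frames = sum(fl$fd$censor),
    mean_abs_error = mean(abs(fl$betas - planted)),
    max_abs_t_of_error = max(abs(fl$betas - planted) /
                               (sd(planted) / sqrt(length(planted)))))
  if (run == 1L) {
    tm <- t_contrast(fl$fit, as.numeric(colnames(fl$design$X) == "SweT"))
    write_volume_nifti(array(tm$t, dim = c(10, 10, 8)),
                       "results/firstlevel/sub-01_run-1_SweT_tmap.nii.gz")
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/firstlevel/recovery.csv", row.names = FALSE)
cat("Run-wise GLM recovery of planted amplitudes:\n")
print(tab, row.names = FALSE)
cat("Mean absolute beta error is noise-limited;",
    "a censored frame contributes nothing to the betas.\n")
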