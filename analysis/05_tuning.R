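#!/usr/bin/env Rscript
# Tuning-index overlap analysis: per subject, savoury-minus-sweet T
# difference maps per modality; their voxelwise Pearson correlation is the
# subject's tuning overlap, related across subjects to crossmodal decoding
# accuracy. Planting a spread of overlap weights across subjects makes the
# expected positive relation recoverable.

library(flavdecode)

seed <- as.integer(commandArgs(TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results", showWarnings = FALSE)

alphas <- seq(0.05, 0.95, length.out = 25)
cohort <- simulate_cohort(25L, synth_config(grid = c(10L, 10L, 8L),
                                            amp = 0.3, sigma_noise = 0.5),
                          seed = child_seed(seed, 7L), alpha = alphas,
                          n_sessions = 1L)

overlaps <- vapply(cohort, subject_tuning_overlap, numeric(1))
acc <- vapply(cohort, function(d)
  decode_roi(d, NULL, "crossmodal")$mean_acc, numeric(1))
tab <- data.frame(subject = seq_along(cohort), planted_alpha = alphas,
                  overlap_r = overlaps, crossmodal_accuracy = acc)
write.csv(tab, "results/tuning_overlap.csv", row.names = FALSE)

rel <- overlap_vs_accuracy(overlaps, acc)
cat(sprintf("Tuning overlap vs crossmodal accuracy: r = %.3f, p = %.4g (n = 25)\n",
            rel$r, rel$p))
cat("Per-subject overlap tracks the planted crossmodal weight:",
    sprintf("cor(alpha, overlap) = %.3f\n", cor(alphas, overlaps)))
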