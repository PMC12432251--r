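#!/usr/bin/env Rscript
# Simulate the study-scale synthetic cohort: 25 subjects, 2 sessions of 6
# runs, 5 conditions (SweT, SavT, SweO, SavO, ArtS), with crossmodal
# pattern overlap 0.5, session-1-dominant run-wise drift, and partial
# redraw of taste patterns between days. Writes one subject's betas as
# NIfTI + manifest (as a format exemplar), the full cohort ratings table,
# and an example event schedule.

library(flavdecode)

seed <- as.integer(commandArgs(TRUE)[1])
if (is.na(seed)) seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(grid = c(10L, 10L, 8L))
cohort <- simulate_cohort(4L, cfg, seed = seed)   # exemplar subset on disk
write_beta_dataset(cohort[[1L]], "results/data/sub-01")

sched <- make_design_events(seed = seed, run_id = 1L, session_id = 1L)
write_events_tsv(sched, "results/data/sub-01_ses-1_run-1_events.tsv")

ratings <- simulate_ratings(25L, seed = seed + 1L)
write.csv(ratings, "results/data/ratings.csv", row.names = FALSE)

mb <- sched$events[sched$events$event_class == "miniblock", ]
cat("Simulated cohort exemplar written under results/data/\n")
cat(sprintf("  schedule: %d mini-blocks, %s repetitions per condition\n",
            nrow(mb), paste(unique(table(mb$trial_type)), collapse = "/")))
cat(sprintf("  betas: %d samples x %d voxels per subject\n",
            nrow(cohort[[1]]$values), ncol(cohort[[1]]$values)))
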