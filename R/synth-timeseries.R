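#' Configuration of the BOLD forward model
#'
#' @param n_frames frames per run.
#' @param tr_s repetition time in seconds.
#' @param noise_sd white-noise SD.
#' @param drift_amp amplitude of a slow cosine scanner drift (0 disables).
#' @param drift_period_s period of the slow drift in seconds.
#' @param motion_sd SD of the random-walk motion trace increments
#'   (translations in mm; rotations scaled down by 100).
#' @param spike_frames frames at which sustained motion offsets are planted.
#' @param spike_mm size of each planted translation offset in mm.
#' @param rinse_amp uniform rinse response amplitude.
#' @param baseline constant signal baseline added to every voxel.
#' @return list of class `ts_config`.
#' @export
ts_config <- function(n_frames = 228L, tr_s = 2, noise_sd = 1,
                      drift_amp = 0, drift_period_s = 300, motion_sd = 0,
                      spike_frames = integer(0), spike_mm = 1.5,
                      rinse_amp = 0, baseline = 100) {
  stopifnot(n_frames >= 1L, tr_s > 0, noise_sd >= 0, drift_amp >= 0,
            motion_sd >= 0, all(spike_frames >= 1L),
            all(spike_frames <= n_frames))
  structure(list(n_frames = as.integer(n_frames), tr_s = tr_s,
                 noise_sd = noise_sd, drift_amp = drift_amp,
                 drift_period_s = drift_period_s, motion_sd = motion_sd,
                 spike_frames = as.integer(spike_frames), spike_mm = spike_mm,
                 rinse_amp = rinse_amp, baseline = baseline),
            class = "ts_config")
}

#' Simulate a 4D BOLD run from a schedule and planted patterns
#'
#' Forward model for the first-level GLM: condition boxcars convolved with
#' the canonical HRF scaled by planted voxel amplitudes (flavour component
#' plus modality offset), a constant baseline, optional slow scanner drift
#' and white noise, plus a matching motion-parameter table with optional
#' planted sustained displacements (spikes) whose framewise displacement
#' equals `spike_mm` at the spike frame.
#'
#' @param schedule an [make_design_events()] schedule.
#' @param patterns a [simulate_patterns()] result.
#' @param config a [ts_config()].
#' @param seed integer RNG seed (optional).
#' @return list of class `bold_run` with `data` (4D array x,y,z,frames),
#'   `tr_s`, `motion`, `run_id`, `session_id`, and the planted
#'   `amplitudes` (voxels x conditions) for recovery checks.
#' @export
simulate_timeseries <- function(schedule, patterns, config = ts_config(),
                                seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"),
            inherits(patterns, "subject_patterns"))
  ev <- schedule$events
  run_s <- config$n_frames * config$tr_s
  if (max(ev$onset + ev$duration) > run_s)
    stop("schedule (", max(ev$onset + ev$duration), " s) longer than run (",
         run_s, " s)")
  with_seed(seed, {
    grid <- patterns$config$grid
    V <- prod(grid)
    mb <- ev[ev$event_class == "miniblock", , drop = FALSE]
    conds <- unique(mb$trial_type)

    amp <- matrix(0, nrow = V, ncol = length(conds),
                  dimnames = list(NULL, conds))
    for (cn in conds) {
      flav <- patterns$components[[cn]] %||% numeric(V)
      off <- if (cn %in% flavour_conditions()$label)
        switch(condition_modality(cn), taste = patterns$o_taste,
               odour = patterns$o_odour, control = numeric(V))
      else numeric(V)
      amp[, cn] <- flav + off
    }

    X <- vapply(conds, function(cn) {
      e <- mb[mb$trial_type == cn, , drop = FALSE]
      hrf_regressor(e$onset, e$duration, config$n_frames, config$tr_s)
    }, numeric(config$n_frames))
    Y <- X %*% t(amp)                       # frames x voxels
    ri <- ev[ev$event_class == "rinse", , drop = FALSE]
    if (nrow(ri) && config$rinse_amp != 0) {
      xr <- hrf_regressor(ri$onset, ri$duration, config$n_frames, config$tr_s)
      Y <- Y + config$rinse_amp * xr
    }
    Y <- Y + config$baseline
    if (config$drift_amp > 0) {
      t_s <- (seq_len(config$n_frames) - 1L) * config$tr_s
      Y <- Y + config$drift_amp * cos(2 * pi * t_s / config$drift_period_s)
    }
    if (config$noise_sd > 0)
      Y <- Y + matrix(rnorm(length(Y), 0, config$noise_sd), nrow = nrow(Y))

    motion <- matrix(0, nrow = config$n_frames, ncol = 6L,
                     dimnames = list(NULL, c("tx", "ty", "tz",
                                             "rx", "ry", "rz")))
    if (config$motion_sd > 0) {
      steps <- matrix(rnorm(config$n_frames * 6L, 0, config$motion_sd),
                      ncol = 6L)
      steps[, 4:6] <- steps[, 4:6] / 100   # rotations in rad, much smaller
      motion <- apply(steps, 2, cumsum)
      motion[1L, ] <- 0
      colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    }
    for (fr in config$spike_frames)
      motion[fr:config$n_frames, 1L] <- motion[fr:config$n_frames, 1L] +
        config$spike_mm

    structure(list(data = array(t(Y), dim = c(grid, config$n_frames)),
                   tr_s = config$tr_s, motion = motion,
                   run_id = schedule$run_id, session_id = schedule$session_id,
                   amplitudes = amp),
              class = "bold_run")
  })
}
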