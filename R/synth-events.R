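#' Configuration for simulated event schedules
#'
#' Defaults mirror the block design of the flavour paradigm: 15 mini-blocks
#' per run (3 repetitions of each of the 5 conditions), 16 s of stimulation
#' per mini-block followed by a 4 s rinse, inter-trial intervals drawn
#' uniformly from 8-12 s, and no condition occurring three times in a row.
#'
#' @param conditions character vector of condition labels.
#' @param reps_per_condition mini-block repetitions per condition per run.
#' @param miniblock_s stimulation duration in seconds.
#' @param rinse_s rinse duration in seconds.
#' @param iti_range_s length-2 numeric, uniform ITI bounds in seconds.
#' @param lead_in_s onset of the first mini-block.
#' @param run_length_s total run length in seconds (228 frames at TR 2 s).
#' @param max_retries rejection-sampling cap for the ordering constraint.
#' @return list of class `event_config`.
#' @export
event_config <- function(conditions = flavour_conditions()$label,
                         reps_per_condition = 3L,
                         miniblock_s = 16,
                         rinse_s = 4,
                         iti_range_s = c(8, 12),
                         lead_in_s = 0,
                         run_length_s = 456,
                         max_retries = 1e4) {
  stopifnot(length(conditions) >= 1L, reps_per_condition >= 1L,
            length(iti_range_s) == 2L, iti_range_s[1] <= iti_range_s[2],
            iti_range_s[1] >= 0, miniblock_s > 0, rinse_s >= 0,
            run_length_s > 0)
  structure(list(conditions = conditions,
                 reps_per_condition = as.integer(reps_per_condition),
                 miniblock_s = miniblock_s, rinse_s = rinse_s,
                 iti_range_s = iti_range_s, lead_in_s = lead_in_s,
                 run_length_s = run_length_s,
                 max_retries = as.integer(max_retries)),
            class = "event_config")
}

# TRUE iff no label occurs at 3 consecutive positions
valid_ordering <- function(ord) {
  n <- length(ord)
  if (n < 3L) return(TRUE)
  !any(ord[-c(1L, 2L)] == ord[-c(n - 1L, n)] & ord[-c(1L, n)] == ord[-c(n - 1L, n)])
}

#' Simulate a pseudo-randomised run event schedule
#'
#' Draws a mini-block ordering by rejection sampling until no condition is
#' repeated consecutively more than once, then lays out each mini-block as
#' stimulation followed by a rinse and a uniform ITI. Fails explicitly if no
#' valid ordering (or no schedule fitting the run) is found within the retry
#' budget.
#'
#' @param config an [event_config()].
#' @param seed integer RNG seed (optional).
#' @param run_id,session_id identifiers stored with the schedule.
#' @return list of class `event_schedule` with elements `events` (data frame
#'   with `onset`, `duration`, `trial_type`, `event_class`), `run_id`,
#'   `session_id`, `run_length_s`.
#' @export
make_design_events <- function(config = event_config(), seed = NULL,
                               run_id = 1L, session_id = 1L) {
  with_seed(seed, {
    labels <- rep(config$conditions, each = config$reps_per_condition)
    n_blocks <- length(labels)
    for (try in seq_len(config$max_retries)) {
      ord <- sample(labels)
      if (!valid_ordering(ord)) next
      itis <- runif(n_blocks - 1L, config$iti_range_s[1], config$iti_range_s[2])
      block_len <- config$miniblock_s + config$rinse_s
      onsets <- config$lead_in_s +
        c(0, cumsum(rep(block_len, n_blocks - 1L) + itis))
      run_end <- onsets[n_blocks] + block_len
      if (run_end > config$run_length_s) next
      ev <- data.frame(
        onset = c(onsets, onsets + config$miniblock_s),
        duration = c(rep(config$miniblock_s, n_blocks),
                     rep(config$rinse_s, n_blocks)),
        trial_type = c(ord, rep("rinse", n_blocks)),
        event_class = rep(c("miniblock", "rinse"), each = n_blocks),
        stringsAsFactors = FALSE
      )
      ev <- ev[order(ev$onset), , drop = FALSE]
      rownames(ev) <- NULL
      return(structure(list(events = ev, run_id = as.integer(run_id),
                            session_id = as.integer(session_id),
                            run_length_s = config$run_length_s),
                       class = "event_schedule"))
    }
    stop("make_design_events: no valid schedule found within ",
         config$max_retries, " retries; constraint set may be infeasible")
  })
}
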