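#' Simulate run-wise beta images for one subject
#'
#' Composes each sample (one per condition per run per session) as
#' `baseline + flavour component + modality offset + run-wise random-walk
#' drift + noise`. The drift walk restarts at zero in each session with a
#' per-session step SD (stronger drift in session 1 by default); taste
#' patterns are partially redrawn in session 2 with mixing weight
#' `rho_session`, degrading across-day taste decoding while leaving odour
#' patterns stable.
#'
#' @param patterns a [simulate_patterns()] result.
#' @param n_runs runs per session.
#' @param n_sessions number of sessions (1 or 2).
#' @param seed integer RNG seed (optional).
#' @param subject subject identifier stored in the metadata.
#' @param conditions condition labels to simulate.
#' @return a [beta_dataset()].
#' @export
simulate_betas <- function(patterns, n_runs = 6L, n_sessions = 2L,
                           seed = NULL, subject = 1L,
                           conditions = flavour_conditions()$label) {
  stopifnot(inherits(patterns, "subject_patterns"),
            n_runs >= 1L, n_sessions %in% 1:2)
  cfg <- patterns$config
  with_seed(seed, {
    V <- prod(cfg$grid)
    sig <- if (is.null(cfg$signal_mask)) rep(TRUE, V) else as.logical(cfg$signal_mask)

    comp_by_session <- list(`1` = patterns$components)
    if (n_sessions == 2L) {
      rho <- cfg$rho_session
      redraw <- function(old) {
        fresh <- numeric(V)
        fresh[sig] <- rnorm(sum(sig), 0, cfg$amp)
        rho * old + sqrt(1 - rho^2) * fresh
      }
      s2 <- patterns$components
      s2$SweT <- redraw(s2$SweT)   # taste patterns unstable across days
      s2$SavT <- redraw(s2$SavT)
      comp_by_session$`2` <- s2
    }

    offset_of <- function(cond) {
      switch(condition_modality(cond),
             taste = patterns$o_taste, odour = patterns$o_odour,
             control = numeric(V))
    }

    n_cond <- length(conditions)
    values <- matrix(NA_real_, nrow = n_sessions * n_runs * n_cond, ncol = V)
    meta <- data.frame(subject = subject, session = NA_integer_,
                       run = NA_integer_, condition = NA_character_,
                       stringsAsFactors = FALSE)[rep(1L, nrow(values)), ]
    row <- 0L
    for (s in seq_len(n_sessions)) {
      comps <- comp_by_session[[as.character(s)]]
      drift <- numeric(V)
      for (r in seq_len(n_runs)) {
        if (r > 1L && cfg$sigma_drift[s] > 0)
          drift <- drift + rnorm(V, 0, cfg$sigma_drift[s])
        for (cond in conditions) {
          row <- row + 1L
          flav <- if (cond %in% names(comps)) comps[[cond]] else numeric(V)
          noise <- if (cfg$sigma_noise > 0) rnorm(V, 0, cfg$sigma_noise) else 0
          values[row, ] <- patterns$baseline + flav + offset_of(cond) +
            drift + noise
          meta$session[row] <- s; meta$run[row] <- r; meta$condition[row] <- cond
        }
      }
    }
    rownames(meta) <- NULL
    beta_dataset(values, meta, cfg$grid, cfg$voxel_size_mm)
  })
}

#' Simulate a cohort of subjects' beta datasets
#'
#' Draws independent subject patterns (optionally with per-subject overlap
#' `alpha`) and their run-wise betas. Child seeds are fanned out
#' deterministically from `seed`, so the cohort is reproducible as a whole
#' and per subject.
#'
#' @param n_subjects number of subjects.
#' @param config a [synth_config()]; `config$alpha` is overridden per
#'   subject when `alpha` is a vector.
#' @param seed integer RNG seed.
#' @param alpha optional numeric vector (length 1 or `n_subjects`) of
#'   per-subject overlap weights.
#' @param n_runs,n_sessions passed to [simulate_betas()].
#' @return list of `beta_dataset` objects, one per subject.
#' @export
simulate_cohort <- function(n_subjects, config = synth_config(), seed = 1L,
                            alpha = NULL, n_runs = 6L, n_sessions = 2L) {
  stopifnot(n_subjects >= 1L)
  if (!is.null(alpha)) alpha <- rep_len(alpha, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    if (!is.null(alpha)) cfg$alpha <- alpha[i]
    pat <- simulate_patterns(cfg, seed = child_seed(seed, 2L * i))
    simulate_betas(pat, n_runs = n_runs, n_sessions = n_sessions,
                   seed = child_seed(seed, 2L * i + 1L), subject = i)
  })
}

#' Simulate pleasantness and intensity ratings
#'
#' Per-subject hedonic ratings for the four flavour stimuli on the -5..5
#' visual-analogue scale, with configurable means per flavour and a common
#' SD; values are clamped to the scale bounds.
#'
#' @param n_subjects number of subjects.
#' @param mean_sweet,mean_savoury pleasantness means.
#' @param sd rating SD.
#' @param intensity_mean,intensity_sd intensity distribution.
#' @param n_sessions sessions to emit rows for.
#' @param seed integer RNG seed (optional).
#' @return data frame with columns `subject`, `session`, `condition`,
#'   `pleasantness`, `intensity`.
#' @export
simulate_ratings <- function(n_subjects, mean_sweet = 2, mean_savoury = 1,
                             sd = 1, intensity_mean = 2, intensity_sd = 1,
                             n_sessions = 2L, seed = NULL) {
  with_seed(seed, {
    conds <- c("SweT", "SavT", "SweO", "SavO")
    g <- expand.grid(subject = seq_len(n_subjects),
                     session = seq_len(n_sessions),
                     condition = conds, stringsAsFactors = FALSE)
    mu <- ifelse(condition_flavour(g$condition) == "sweet",
                 mean_sweet, mean_savoury)
    clamp <- function(x) pmin(5, pmax(-5, x))
    g$pleasantness <- clamp(rnorm(nrow(g), mu, sd))
    g$intensity <- clamp(rnorm(nrow(g), intensity_mean, intensity_sd))
    g[order(g$subject, g$session, g$condition), , drop = FALSE]
  })
}

#' Absolute sweet-savoury hedonic difference per subject
#'
#' Summarises a ratings table into one value per subject: the absolute
#' difference between mean sweet and mean savoury pleasantness, the
#' covariate used to check that crossmodal decoding is not hedonically
#' driven.
#'
#' @param ratings a [simulate_ratings()]-style data frame.
#' @return data frame with columns `subject`, `hedonic_diff`.
#' @export
hedonic_differences <- function(ratings) {
  stopifnot(all(c("subject", "condition", "pleasantness") %in% names(ratings)))
  flav <- condition_flavour(ratings$condition)
  agg <- tapply(ratings$pleasantness, list(ratings$subject, flav), mean)
  data.frame(subject = rownames(agg),
             hedonic_diff = abs(agg[, "sweet"] - agg[, "savoury"]),
             row.names = NULL)
}
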