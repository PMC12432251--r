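#' Canonical double-gamma haemodynamic response function
#'
#' Samples the canonical HRF (response gamma with delay 6 s, undershoot
#' gamma with delay 16 s, unit dispersions, response:undershoot ratio 6)
#' over 32 s at resolution `dt_s`, peak-normalised to 1.
#'
#' @param dt_s sampling interval in seconds.
#' @return numeric vector of `ceiling(32 / dt_s)` kernel samples.
#' @export
canonical_hrf <- function(dt_s) {
  stopifnot(dt_s > 0)
  t <- (seq_len(ceiling(32 / dt_s)) - 1L) * dt_s
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# 1D discrete convolution of x with kernel k, aligned at the start of x
conv_causal <- function(x, k) {
  out <- convolve(x, rev(k), type = "open")
  out[seq_along(x)]
}

#' Sampled (unconvolved) boxcar regressor
#'
#' @param onsets,durations event timing in seconds.
#' @param n_frames number of frames.
#' @param tr_s repetition time in seconds.
#' @return 0/1 vector over frame acquisition times `(0:(n-1)) * tr_s`.
#' @export
boxcar_regressor <- function(onsets, durations, n_frames, tr_s) {
  t <- (seq_len(n_frames) - 1L) * tr_s
  x <- numeric(n_frames)
  for (i in seq_along(onsets))
    x[t >= onsets[i] & t < onsets[i] + durations[i]] <- 1
  x
}

# HRF-convolved boxcar sampled at frame times, built on an upsampled grid
hrf_regressor <- function(onsets, durations, n_frames, tr_s, upsample = 16L) {
  dt <- tr_s / upsample
  n_hi <- n_frames * upsample
  u <- numeric(n_hi)
  t_hi <- (seq_len(n_hi) - 1L) * dt
  for (i in seq_along(onsets))
    u[t_hi >= onsets[i] & t_hi < onsets[i] + durations[i]] <- 1
  conv_causal(u, canonical_hrf(dt))[(seq_len(n_frames) - 1L) * upsample + 1L]
}

#' Discrete-cosine high-pass basis
#'
#' Cosine regressors whose periods exceed `cutoff_s`; the column count is
#' `floor(2 * n_frames * tr_s / cutoff_s)` (7 for a 456 s run at the
#' default 128 s cutoff). The constant term is left to the run intercept.
#'
#' @param n_frames number of frames.
#' @param tr_s repetition time in seconds.
#' @param cutoff_s high-pass cutoff period in seconds.
#' @return matrix `n_frames x K` (possibly zero columns).
#' @export
dct_basis <- function(n_frames, tr_s, cutoff_s = 128) {
  K <- floor(2 * n_frames * tr_s / cutoff_s)
  n <- n_frames
  if (K < 1L) return(matrix(numeric(0), nrow = n, ncol = 0))
  ks <- seq_len(K)
  mat <- vapply(ks, function(k)
    sqrt(2 / n) * cos(pi * (2 * seq_len(n) - 1) * k / (2 * n)),
    numeric(n))
  colnames(mat) <- paste0("hpf_", ks)
  mat
}

#' Build a first-level design matrix
#'
#' Condition mini-block boxcars (and the rinse regressor of no interest)
#' convolved with the canonical HRF, six motion parameters, one-hot spike
#' regressors for censored frames, a discrete-cosine high-pass basis
#' (cutoff 128 s) and a run intercept (last column).
#'
#' @param schedule an [make_design_events()] schedule.
#' @param n_frames number of frames in the run.
#' @param tr_s repetition time in seconds.
#' @param motion optional frames x 6 motion matrix.
#' @param fd optional [compute_fd()] result supplying censor flags.
#' @param hpf_s high-pass cutoff in seconds (0 disables).
#' @param upsample microtime upsampling factor for HRF convolution.
#' @return list of class `design_matrix` with elements `X`, `names`,
#'   `condition_cols` (named indices of condition regressors), `n_frames`,
#'   `tr_s`.
#' @export
build_design_matrix <- function(schedule, n_frames, tr_s = 2, motion = NULL,
                                fd = NULL, hpf_s = 128, upsample = 16L) {
  stopifnot(inherits(schedule, "event_schedule"), n_frames >= 1L)
  ev <- schedule$events
  if (max(ev$onset + ev$duration) > n_frames * tr_s)
    stop("events extend beyond the run (", max(ev$onset + ev$duration),
         " s > ", n_frames * tr_s, " s)")
  mb <- ev[ev$event_class == "miniblock", , drop = FALSE]
  known <- flavour_conditions()$label
  conds <- unique(mb$trial_type)
  conds <- c(intersect(known, conds), setdiff(conds, known))

  cols <- list(); nms <- character(0)
  for (cn in conds) {
    e <- mb[mb$trial_type == cn, , drop = FALSE]
    cols[[length(cols) + 1L]] <-
      hrf_regressor(e$onset, e$duration, n_frames, tr_s, upsample)
    nms <- c(nms, cn)
  }
  ri <- ev[ev$event_class == "rinse", , drop = FALSE]
  if (nrow(ri)) {
    cols[[length(cols) + 1L]] <-
      hrf_regressor(ri$onset, ri$duration, n_frames, tr_s, upsample)
    nms <- c(nms, "rinse")
  }
  condition_cols <- seq_along(conds)
  names(condition_cols) <- conds

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_frames, ncol(motion) == 6L)
    # constant motion traces duplicate the intercept; keep informative ones
    for (k in 1:6) {
      if (sd(motion[, k]) > 0) {
        cols[[length(cols) + 1L]] <- motion[, k]
        nms <- c(nms, paste0("motion_", k))
      }
    }
  }
  if (!is.null(fd)) {
    flagged <- which(fd$censor)
    for (fr in flagged) {
      s <- numeric(n_frames); s[fr] <- 1
      cols[[length(cols) + 1L]] <- s
    }
    if (length(flagged)) nms <- c(nms, paste0("spike_", flagged))
  }
  if (hpf_s > 0) {
    B <- dct_basis(n_frames, tr_s, hpf_s)
    if (ncol(B)) {
      for (k in seq_len(ncol(B))) cols[[length(cols) + 1L]] <- B[, k]
      nms <- c(nms, colnames(B))
    }
  }
  cols[[length(cols) + 1L]] <- rep(1, n_frames)
  nms <- c(nms, "intercept")

  X <- do.call(cbind, cols)
  colnames(X) <- nms
  structure(list(X = X, names = nms, condition_cols = condition_cols,
                 n_frames = n_frames, tr_s = tr_s),
            class = "design_matrix")
}
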