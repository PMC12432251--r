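#' Framewise displacement from rigid-body motion parameters
#'
#' Backward-difference framewise displacement: the sum of absolute
#' translation increments plus the rotation increments converted to arc
#' length at a reference head radius. The first frame has FD 0. Frames are
#' flagged for censoring at FD strictly greater than `threshold_mm`.
#'
#' @param motion frames x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param rotation_radius_mm radius used to convert rotations to mm.
#' @param threshold_mm censoring threshold in mm (strict inequality).
#' @return data frame of class `fd_series` with columns `fd`, `censor`.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50, threshold_mm = 1) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  d <- diff(motion)
  fd <- c(0, rowSums(abs(d[, 1:3, drop = FALSE])) +
            rotation_radius_mm * rowSums(abs(d[, 4:6, drop = FALSE])))
  out <- data.frame(fd = fd, censor = fd > threshold_mm)
  class(out) <- c("fd_series", class(out))
  out
}

#' Run exclusion by censored-frame fraction
#'
#' A run is excluded when strictly more than `max_fraction` of its frames
#' are censored (e.g. 23/228 = 0.1009 is excluded at the 10% criterion,
#' 22/228 = 0.0965 is kept).
#'
#' @param fd_list list of [compute_fd()] results, one per run.
#' @param max_fraction maximum tolerated censored fraction.
#' @return logical vector: TRUE for kept runs.
#' @export
exclude_runs <- function(fd_list, max_fraction = 0.10) {
  vapply(fd_list, function(f) {
    stopifnot(is.data.frame(f), "censor" %in% names(f))
    mean(f$censor) <= max_fraction
  }, logical(1))
}

#' Grand-mean scaling of a run
#'
#' Rescales a run so that its mean over in-mask voxels and all frames
#' equals 100, making betas comparable across runs.
#'
#' @param run a `bold_run` or a voxels x frames matrix.
#' @param mask optional logical volume/vector selecting in-mask voxels.
#' @return the input with values scaled; errors on non-positive run mean.
#' @export
grand_mean_scale <- function(run, mask = NULL) {
  Y <- run_matrix(run)
  idx <- mask_indices(mask, nrow(Y))
  m <- mean(Y[idx, , drop = FALSE])
  if (!is.finite(m) || m <= 0)
    stop("grand_mean_scale: run mean is ", m, "; must be positive")
  set_run_matrix(run, Y * (100 / m))
}

#' Linear-model-of-global-signal detrending
#'
#' Regresses every voxel's time series on an intercept and the global mean
#' signal (frame-wise mean over in-mask voxels) and returns the residuals
#' plus the voxel mean, removing global fluctuations while preserving each
#' voxel's mean level.
#'
#' @param run a `bold_run` or a voxels x frames matrix.
#' @param mask optional logical volume/vector defining the global signal.
#' @return the input with detrended values; the global signal used is
#'   attached as attribute `"global_signal"`.
#' @export
lmgs_detrend <- function(run, mask = NULL) {
  Y <- run_matrix(run)
  idx <- mask_indices(mask, nrow(Y))
  gs <- colMeans(Y[idx, , drop = FALSE])
  X <- cbind(1, gs)
  B <- solve(crossprod(X), crossprod(X, t(Y)))   # 2 x V
  resid <- t(Y) - X %*% B                        # frames x V
  out <- t(resid) + rowMeans(Y)
  res <- set_run_matrix(run, out)
  attr(res, "global_signal") <- gs
  res
}

# helpers to view a bold_run (4D array) as voxels x frames and back
run_matrix <- function(run) {
  if (inherits(run, "bold_run")) {
    d <- dim(run$data)
    matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
  } else as.matrix(run)
}
set_run_matrix <- function(run, Y) {
  if (inherits(run, "bold_run")) {
    run$data <- array(Y, dim = dim(run$data))
    run
  } else Y
}

# normalised 1D convolution preserving constants at the edges
conv1d_norm <- function(x, k) {
  h <- (length(k) - 1L) / 2L
  num <- convolve(c(rep(0, h), x, rep(0, h)), rev(k), type = "filter")
  den <- convolve(c(rep(0, h), rep(1, length(x)), rep(0, h)), rev(k),
                  type = "filter")
  num / den
}

#' Isotropic Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis, renormalised at the volume edges so constant volumes are
#' unchanged. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm full width at half maximum in millimetres.
#' @param voxel_size_mm isotropic voxel size in millimetres.
#' @return smoothed array of the same dimension.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = 2) {
  stopifnot(length(dim(volume)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- volume
  for (axis in 1:3) {
    out <- apply(out, setdiff(1:3, axis), conv1d_norm, k = k)
    # apply() returns the convolved axis first; rotate it back into place
    out <- aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  out
}

#' Fit an ordinary-least-squares GLM per voxel
#'
#' @param Y frames x voxels data matrix.
#' @param design a [build_design_matrix()] result (or plain matrix).
#' @return list of class `glm_fit` with `beta` (regressors x voxels),
#'   `sigma2` (residual variance per voxel), `df` (frames - rank),
#'   `XtX_inv`, and the design. Errors on rank-deficient designs, naming
#'   the offending columns.
#' @export
fit_glm <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("fit_glm: design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - qx$rank
  sigma2 <- if (df > 0) colSums(resid^2) / df else rep(NA_real_, ncol(Y))
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 XtX_inv = chol2inv(chol(crossprod(X))),
                 design = design),
            class = "glm_fit")
}

#' Voxelwise T statistic for a contrast
#'
#' `T = c'beta / sqrt(sigma2 * c' (X'X)^-1 c)` per voxel; voxels with zero
#' residual variance get T = 0.
#'
#' @param fit a [fit_glm()] result.
#' @param weights contrast weight vector (length = number of regressors).
#' @return list of class `t_map` with `t` (per voxel) and `df`.
#' @export
t_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"),
            length(weights) == nrow(fit$beta))
  num <- drop(crossprod(weights, fit$beta))
  cvc <- drop(t(weights) %*% fit$XtX_inv %*% weights)
  den <- sqrt(fit$sigma2 * cvc)
  t <- ifelse(den > 0, num / den, 0)
  structure(list(t = t, df = fit$df), class = "t_map")
}

#' First-level GLM on one simulated (or real) run
#'
#' Convenience wrapper chaining framewise-displacement censoring, optional
#' grand-mean scaling and global-signal detrending, design construction and
#' OLS estimation, returning the condition betas as a matrix.
#'
#' @param run a `bold_run`.
#' @param schedule the run's event schedule.
#' @param mask optional analysis mask.
#' @param scale,detrend toggles for grand-mean scaling and LMGS detrending.
#' @param fd_threshold_mm censoring threshold.
#' @param hpf_s high-pass cutoff (0 disables).
#' @return list with `betas` (conditions x voxels), `fit`, `fd`, `design`.
#' @export
run_first_level <- function(run, schedule, mask = NULL, scale = FALSE,
                            detrend = FALSE, fd_threshold_mm = 1,
                            hpf_s = 128) {
  stopifnot(inherits(run, "bold_run"))
  fd <- compute_fd(run$motion, threshold_mm = fd_threshold_mm)
  if (scale) run <- grand_mean_scale(run, mask)
  if (detrend) run <- lmgs_detrend(run, mask)
  n_frames <- dim(run$data)[4]
  design <- build_design_matrix(schedule, n_frames, tr_s = run$tr_s,
                                motion = run$motion, fd = fd, hpf_s = hpf_s)
  fit <- fit_glm(t(run_matrix(run)), design)
  betas <- fit$beta[design$condition_cols, , drop = FALSE]
  rownames(betas) <- names(design$condition_cols)
  list(betas = betas, fit = fit, fd = fd, design = design)
}
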