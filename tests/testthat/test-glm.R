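test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  expect_equal(length(h), ceiling(32 / 0.1))
  expect_lt(abs(h[1]), 1e-6)
  tpk <- (which.max(h) - 1) * 0.1
  expect_gte(tpk, 4); expect_lte(tpk, 6)
  expect_equal(max(h), 1)
  expect_equal(length(canonical_hrf(2)), 16L)
})

test_that("unconvolved boxcars cover duration/TR frames per event", {
  s <- make_design_events(seed = 1)
  mb <- s$events[s$events$event_class == "miniblock" &
                   s$events$trial_type == "SweT", ]
  x <- boxcar_regressor(mb$onset, mb$duration, 228, 2)
  expect_equal(sum(x), nrow(mb) * 16 / 2)
})

test_that("discrete-cosine basis size follows the cutoff formula", {
  expect_equal(ncol(dct_basis(228, 2, 128)), 7L)  # 456 s run
  expect_equal(ncol(dct_basis(10, 2, 128)), 0L)
  # all DCT periods exceed the cutoff
  B <- dct_basis(228, 2, 128)
  for (k in seq_len(ncol(B)))
    expect_gt(2 * 228 * 2 / k, 128)
})

test_that("framewise displacement follows the backward-difference definition", {
  m <- matrix(0, 100, 6)
  fd0 <- compute_fd(m)
  expect_true(all(fd0$fd == 0))
  expect_equal(sum(fd0$censor), 0L)

  m1 <- m; m1[50:100, 1] <- 1.5
  fd1 <- compute_fd(m1)
  expect_equal(fd1$fd[50], 1.5)
  expect_true(fd1$censor[50])
  expect_equal(sum(fd1$censor), 1L)

  m2 <- m; m2[50:100, 4] <- 0.02  # 0.02 rad * 50 mm = 1.0, strict > keeps it
  fd2 <- compute_fd(m2, rotation_radius_mm = 50)
  expect_equal(fd2$fd[50], 1.0)
  expect_false(fd2$censor[50])
  expect_equal(fd2$fd[1], 0)
})

test_that("runs are excluded above (strictly) 10% censored frames", {
  fake <- function(k, n = 228) {
    data.frame(fd = rep(0, n), censor = c(rep(TRUE, k), rep(FALSE, n - k)))
  }
  keep <- exclude_runs(list(fake(23), fake(22), fake(0)))
  expect_identical(keep, c(FALSE, TRUE, TRUE))
})

test_that("grand-mean scaling maps the run mean to 100", {
  Y <- matrix(200, nrow = 10, ncol = 20)
  expect_equal(mean(grand_mean_scale(Y)), 100)
  Yc <- matrix(7.3, 5, 4)
  expect_true(all(grand_mean_scale(Yc) == 100))
  Y2 <- matrix(rexp(200) + 50, 10, 20)
  s <- grand_mean_scale(Y2)
  expect_equal(mean(s), 100)
  expect_equal(grand_mean_scale(s), s)  # idempotent at mean 100
  expect_error(grand_mean_scale(matrix(0, 3, 3)), "positive")
})

test_that("global-signal detrending removes the global signal only", {
  set.seed(1)
  gs <- rnorm(50)
  # every voxel equal to the global signal -> constant residual series
  Y <- matrix(rep(gs, each = 6), nrow = 6, byrow = FALSE) + 0 # 6 x 50? build properly
  Y <- matrix(gs, nrow = 6, ncol = 50, byrow = TRUE)
  out <- lmgs_detrend(Y)
  expect_lt(max(abs(sweep(out, 1, rowMeans(out)))), 1e-10)
  # voxel orthogonal to the global signal is unchanged up to its mean
  n <- 40
  g2 <- rnorm(n)
  v <- residuals(lm(rnorm(n) ~ g2))          # orthogonal to g2 and centred
  Y2 <- rbind(matrix(g2, nrow = 9, ncol = n, byrow = TRUE), v + 5)
  out2 <- lmgs_detrend(Y2, mask = c(rep(TRUE, 9), FALSE))
  expect_equal(as.numeric(out2[10, ]), as.numeric(v + 5), tolerance = 1e-6)
  # residual series are uncorrelated with the global signal used
  set.seed(2)
  Y3 <- matrix(rnorm(12 * n), 12, n) + matrix(g2, 12, n, byrow = TRUE)
  out3 <- lmgs_detrend(Y3)
  gs3 <- attr(out3, "global_signal")
  cors <- apply(out3, 1, function(r) cor(r, gs3))
  expect_lt(max(abs(cors)), 1e-8)
})

test_that("gaussian smoothing preserves constants and has the right width", {
  v <- array(3.5, dim = c(9, 9, 9))
  expect_equal(smooth_volume(v, 6, 2), v)
  expect_identical(smooth_volume(v, 0, 2), v)
  # delta input: measure FWHM along one axis
  d <- array(0, dim = c(31, 31, 31)); d[16, 16, 16] <- 1
  sm <- smooth_volume(d, fwhm_mm = 8, voxel_size_mm = 2)
  prof <- sm[, 16, 16]
  half <- max(prof) / 2
  above <- which(prof >= half)
  measured_fwhm_mm <- (max(above) - min(above)) * 2  # voxel size 2
  expect_equal(measured_fwhm_mm, 8, tolerance = 0.3)
})

test_that("design matrices assemble conditions, confounds and intercept", {
  s <- make_design_events(seed = 2)
  motion <- matrix(cumsum(rnorm(228 * 6, sd = 0.001)), 228, 6)
  fd <- compute_fd(motion)
  fd$censor[] <- FALSE
  fd$censor[c(10, 90)] <- TRUE
  X <- build_design_matrix(s, 228, 2, motion = motion, fd = fd)
  expect_equal(sum(grepl("^spike_", X$names)), 2L)
  expect_equal(sum(X$X[, "spike_10"]), 1)
  expect_equal(sum(grepl("^hpf_", X$names)), 7L)
  expect_equal(X$names[length(X$names)], "intercept")
  expect_equal(length(X$condition_cols), 5L)
  expect_true("rinse" %in% X$names)
  # events beyond the run fail
  expect_error(build_design_matrix(s, 60, 2), "beyond")
})

test_that("OLS estimation is exact on noiseless data and reports rank problems", {
  s <- make_design_events(seed = 3)
  X <- build_design_matrix(s, 228, 2)
  set.seed(4)
  b <- matrix(rnorm(ncol(X$X) * 10), ncol = 10)
  fit <- fit_glm(X$X %*% b, X)
  expect_lt(max(abs(fit$beta - b)), 1e-8)
  expect_equal(fit$df, 228 - ncol(X$X))
  # residuals orthogonal to the design
  set.seed(5)
  Y <- matrix(rnorm(228 * 5), 228)
  f2 <- fit_glm(Y, X)
  res <- Y - X$X %*% f2$beta
  expect_lt(max(abs(crossprod(X$X, res))), 1e-6)
  # duplicated column -> explicit failure naming it
  Xbad <- cbind(X$X, dup = X$X[, 1])
  expect_error(fit_glm(Y, Xbad), "rank deficient")
})

test_that("noise-only condition betas are centred on zero", {
  s <- make_design_events(seed = 6)
  X <- build_design_matrix(s, 228, 2)
  set.seed(7)
  Y <- matrix(rnorm(228 * 200), 228)
  fit <- fit_glm(Y, X)
  cond_b <- fit$beta[X$condition_cols, ]
  se <- sd(cond_b) / sqrt(length(cond_b))
  expect_lt(abs(mean(cond_b)), 3 * se)
})

test_that("t contrasts behave like t statistics", {
  s <- make_design_events(seed = 8)
  X <- build_design_matrix(s, 228, 2)
  set.seed(9)
  Y <- matrix(rnorm(228 * 30), 228)
  fit <- fit_glm(Y, X)
  w0 <- rep(0, ncol(X$X))
  expect_true(all(t_contrast(fit, w0)$t == 0))
  w <- w0; w[1] <- 1
  tm <- t_contrast(fit, w)
  expect_equal(t_contrast(fit, -w)$t, -tm$t)
  # single-regressor T^2 equals the F statistic of dropping that regressor
  v <- 3
  full <- lm(Y[, v] ~ 0 + X$X)
  red <- lm(Y[, v] ~ 0 + X$X[, -1])
  Fstat <- anova(red, full)$F[2]
  expect_equal(tm$t[v]^2, Fstat, tolerance = 1e-8)
})

test_that("the GLM recovers planted amplitudes from simulated runs", {
  pat <- tiny_patterns(seed = 10, alpha = 0.6)
  s <- make_design_events(seed = 11)
  run <- simulate_timeseries(s, pat, ts_config(noise_sd = 0), seed = 12)
  fl <- run_first_level(run, s)
  planted <- t(run$amplitudes)[rownames(fl$betas), , drop = FALSE]
  expect_lt(max(abs(fl$betas - planted)), 1e-6)
  # planted spike appears in FD and as a spike regressor
  run2 <- simulate_timeseries(s, pat,
                              ts_config(noise_sd = 0, spike_frames = 77L,
                                        spike_mm = 1.5), seed = 12)
  fl2 <- run_first_level(run2, s)
  expect_equal(fl2$fd$fd[77], 1.5)
  expect_true("spike_77" %in% colnames(fl2$design$X))
  # zero amplitudes, zero noise -> constant series
  pat0 <- tiny_patterns(seed = 13, amp = 0)
  pat0$baseline[] <- 0; pat0$o_taste[] <- 0; pat0$o_odour[] <- 0
  run0 <- simulate_timeseries(s, pat0, ts_config(noise_sd = 0), seed = 14)
  expect_equal(max(run0$data), min(run0$data))
})

test_that("censored frames carry no leverage on condition betas", {
  pat <- tiny_patterns(seed = 15)
  s <- make_design_events(seed = 16)
  run <- simulate_timeseries(s, pat, ts_config(noise_sd = 0.5), seed = 17)
  k <- 120L
  Y <- t(flavdecode:::run_matrix(run))
  fd <- compute_fd(run$motion)
  fd$censor[k] <- TRUE
  X <- build_design_matrix(s, 228, 2, fd = fd)
  fit_spike <- fit_glm(Y, X)
  # oracle: delete the frame instead
  keepr <- setdiff(seq_len(228), k)
  Xdel <- X$X[keepr, setdiff(colnames(X$X), paste0("spike_", k))]
  fit_del <- fit_glm(Y[keepr, ], Xdel)
  cond <- names(X$condition_cols)
  expect_equal(fit_spike$beta[cond, ], fit_del$beta[cond, ],
               tolerance = 1e-8)
})
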