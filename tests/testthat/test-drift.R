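test_that("correlation-distance RDMs hit the canonical values", {
  g <- c(4, 3, 1)
  v1 <- rnorm(12)
  meta <- data.frame(subject = 1, session = 1, run = c(1, 2, 3),
                     condition = c("SweT", "SweT", "SweT"))
  vals <- rbind(v1, v1, -v1 + mean(v1) * 2)
  # row 3 is perfectly anticorrelated with row 1
  d <- beta_dataset(vals, within(meta, run <- c(1, 2, 3)), g)
  rdm <- neural_rdm(d, conditions = "SweT")
  expect_equal(rdm$mat[1, 2], 0, tolerance = 1e-12)
  expect_equal(rdm$mat[1, 3], 2, tolerance = 1e-12)
  expect_equal(unname(diag(rdm$mat)), rep(0, 3))
  expect_equal(rdm$mat, t(rdm$mat))
  # orthogonal vectors sit at distance 1
  set.seed(4)
  x <- rnorm(500); y <- residuals(lm(rnorm(500) ~ x))
  m2 <- data.frame(subject = 1, session = 1, run = 1:2,
                   condition = c("SweT", "SweT"))
  d2 <- beta_dataset(rbind(x, y), m2, c(50, 10, 1))
  expect_equal(neural_rdm(d2, conditions = "SweT")$mat[1, 2], 1,
               tolerance = 1e-9)
})

test_that("RDMs are equivariant under item permutation", {
  d <- tiny_dataset(seed = 5, noise = 0.5, n_sessions = 1L)
  rdm <- neural_rdm(d)
  idx <- which(d$meta$condition != "ArtS")
  per <- sample(seq_along(idx))
  d2 <- subset_samples(d, c(idx[per], setdiff(seq_len(nrow(d$meta)), idx)))
  rdm2 <- neural_rdm(d2)
  expect_equal(rdm2$mat, rdm$mat[per, per], tolerance = 1e-12)
})

test_that("runwise distances are scaled by the largest separation", {
  rd <- runwise_distance(1:6)
  expect_equal(rd[1, 6], 1)
  expect_equal(rd[1, 2], 0.2)
  expect_equal(diag(rd), rep(0, 6))
  expect_equal(runwise_distance(c(2, 5))[1, 2], 1)
})

test_that("drift tables have the closed-form combinatorial row count", {
  for (R in c(3, 4, 6)) {
    for (K in c(2, 4)) {
      conds <- c("SweT", "SavT", "SweO", "SavO")[1:K]
      d <- tiny_dataset(seed = 6, noise = 0.2, n_runs = R, n_sessions = 2L)
      rdm <- neural_rdm(d, conditions = conds)
      tab <- assemble_drift_table(rdm)
      expect_equal(nrow(tab), 2 * choose(R, 2) * K^2)
      expect_true(all(tab$run_dist > 0))
      expect_true(all(tab$flavour_dist %in% 0:1))
      expect_true(all(tab$modality_dist %in% 0:1))
    }
  }
})

test_that("same-run and cross-session pairs never enter the drift table", {
  d <- tiny_dataset(seed = 7, noise = 0.3)
  rdm <- neural_rdm(d)
  tab <- assemble_drift_table(rdm)
  # max scaled distance within each subject-session is 1
  expect_equal(max(tab$run_dist[tab$session == 1]), 1)
  expect_equal(max(tab$run_dist[tab$session == 2]), 1)
  expect_equal(nrow(tab), 2 * choose(6, 2) * 16)
})

test_that("the drift LMM recovers planted run-wise drift", {
  co <- simulate_cohort(6, synth_config(grid = tiny_grid, alpha = 0.5,
                                        amp = 0.3, sigma_noise = 0.4,
                                        sigma_drift = c(0.3, 0.3),
                                        rho_session = 1),
                        seed = 8)
  fit <- fit_drift_lmm(drift_table_cohort(co))
  fx <- fit$fixed
  expect_gt(fx$beta[fx$term == "run_dist"], 0)
  expect_lt(fx$p[fx$term == "run_dist"], 0.05)
  expect_true(all(fx$ci_lo <= fx$beta & fx$beta <= fx$ci_hi))
})

test_that("zero-drift zero-signal data yield null drift effects", {
  co <- simulate_cohort(6, synth_config(grid = tiny_grid, alpha = 0.5,
                                        amp = 0, sigma_noise = 0.5,
                                        sigma_drift = c(0, 0),
                                        rho_session = 1),
                        seed = 9)
  fit <- fit_drift_lmm(drift_table_cohort(co))
  fx <- fit$fixed
  for (term in c("run_dist", "run_dist:session_c"))
    expect_lt(abs(fx$beta[fx$term == term]),
              3 * fx$se[fx$term == term])
})

test_that("within-day vs across-day comparison recovers session instability", {
  co <- simulate_cohort(6, synth_config(grid = tiny_grid, alpha = 0.5,
                                        amp = 0.5, sigma_noise = 0.5,
                                        rho_session = 0.2), seed = 10)
  tab <- decode_within_across(co, modality = "taste")
  fit <- within_vs_across_day(tab)
  b <- fit$fixed
  expect_gt(b$beta[b$term == "partitionwithin"], 0)
  # identical accuracies give a zero effect
  flat <- data.frame(subject = rep(1:5, each = 2),
                     partition = rep(c("within", "across"), 5),
                     accuracy = rep(0.6, 10))
  fit0 <- within_vs_across_day(flat)
  expect_equal(fit0$fixed$beta[fit0$fixed$term == "partitionwithin"], 0,
               tolerance = 1e-8)
})

test_that("single-session subjects are dropped with a warning", {
  co <- simulate_cohort(3, synth_config(grid = tiny_grid, amp = 0.5,
                                        sigma_noise = 0.5), seed = 11)
  co[[3]] <- simulate_betas(tiny_patterns(seed = 12, amp = 0.5, noise = 0.5),
                            n_sessions = 1L, seed = 13, subject = 3L)
  expect_warning(tab <- decode_within_across(co), "single session")
  expect_false(3 %in% tab$subject)
  flat <- data.frame(subject = c(1, 1, 2, 2, 3),
                     partition = c("within", "across", "within", "across",
                                   "within"),
                     accuracy = c(0.6, 0.5, 0.7, 0.6, 0.9))
  expect_warning(fit <- within_vs_across_day(flat), "dropping")
})
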