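test_that("event schedules satisfy the block-design constraints", {
  for (seed in c(1, 7, 123)) {
    s <- make_design_events(seed = seed)
    mb <- s$events[s$events$event_class == "miniblock", ]
    ri <- s$events[s$events$event_class == "rinse", ]
    expect_equal(nrow(mb), 15L)
    expect_true(all(table(mb$trial_type) == 3L))
    expect_true(all(mb$duration == 16))
    expect_true(all(ri$duration == 4))
    # non-overlap and containment
    ev <- s$events[order(s$events$onset), ]
    expect_true(all(diff(ev$onset) >= ev$duration[-nrow(ev)] - 1e-9))
    expect_lte(max(ev$onset + ev$duration), s$run_length_s)
  }
})

test_that("no condition is repeated consecutively more than once", {
  for (seed in 1:400) {
    mb <- make_design_events(seed = seed)$events
    ord <- mb$trial_type[mb$event_class == "miniblock"]
    runs <- rle(ord)$lengths
    expect_true(all(runs <= 2L))
  }
})

test_that("schedules are deterministic given config and seed", {
  expect_identical(make_design_events(seed = 11), make_design_events(seed = 11))
  expect_false(identical(make_design_events(seed = 11)$events$trial_type,
                         make_design_events(seed = 12)$events$trial_type))
})

test_that("a one-condition one-repetition schedule is a single block at onset 0", {
  s <- make_design_events(event_config(conditions = "ArtS",
                                       reps_per_condition = 1L), seed = 1)
  mb <- s$events[s$events$event_class == "miniblock", ]
  expect_equal(nrow(mb), 1L)
  expect_equal(mb$onset, 0)
})

test_that("infeasible ordering constraints fail explicitly", {
  expect_error(make_design_events(event_config(conditions = "SweT",
                                               reps_per_condition = 3L,
                                               max_retries = 50),
                                  seed = 1),
               "retries")
})

test_that("odour flavour components share the taste component by alpha", {
  p1 <- tiny_patterns(seed = 3, alpha = 1, grid = c(12, 12, 11))
  expect_equal(cor(p1$components$SweT, p1$components$SweO), 1)
  expect_equal(cor(p1$components$SavT, p1$components$SavO), 1)
  p0 <- tiny_patterns(seed = 4, alpha = 0, grid = c(12, 12, 11))
  expect_lt(abs(cor(p0$components$SweT, p0$components$SweO)), 0.1)
})

test_that("odour component variance is alpha-invariant", {
  g <- c(25, 20, 20) # 10^4 voxels
  for (a in c(0, 0.4, 0.8)) {
    p <- tiny_patterns(seed = 5, alpha = a, grid = g)
    expect_equal(var(p$components$SweO), var(p$components$SweT),
                 tolerance = 0.05)
  }
  expect_error(synth_config(alpha = 1.2), "alpha")
})

test_that("noise-free drift-free betas are identical across runs and sessions", {
  d <- tiny_dataset(seed = 6, noise = 0, drift = c(0, 0), rho = 1)
  expect_equal(nrow(d$values), 60L)
  for (cond in c("SweT", "SavO", "ArtS")) {
    rows <- d$values[d$meta$condition == cond, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }
})

test_that("random-walk drift increases same-condition distance with run separation", {
  seps <- 1:5
  gap <- replicate(15, {
    d <- tiny_dataset(seed = sample.int(1e6, 1), noise = 0,
                      drift = c(0.5, 0.5), n_sessions = 1L)
    rows <- which(d$meta$condition == "SweT")
    dd <- 1 - cor(t(d$values[rows, ]))
    sapply(seps, function(s) mean(dd[row(dd) - col(dd) == s]))
  })
  m <- rowMeans(gap)
  expect_true(all(diff(m) > 0))
})

test_that("beta simulation is seed-deterministic", {
  expect_identical(tiny_dataset(seed = 9, noise = 0.5)$values,
                   tiny_dataset(seed = 9, noise = 0.5)$values)
})

test_that("ratings respect the scale and configured moments", {
  r0 <- simulate_ratings(5, mean_sweet = 2, mean_savoury = 2, sd = 0, seed = 1)
  h0 <- hedonic_differences(r0)
  expect_true(all(h0$hedonic_diff == 0))
  r2 <- simulate_ratings(5, mean_sweet = 3, mean_savoury = 1, sd = 0, seed = 1)
  expect_true(all(hedonic_differences(r2)$hedonic_diff == 2))
  rb <- simulate_ratings(200, mean_sweet = 1, mean_savoury = 0, sd = 1,
                         seed = 2)
  expect_true(all(rb$pleasantness >= -5 & rb$pleasantness <= 5))
  sw <- rb$pleasantness[condition_flavour(rb$condition) == "sweet"]
  se <- sd(sw) / sqrt(length(sw))
  expect_lt(abs(mean(sw) - 1), 3 * se)
})

test_that("toy ROI masks are boolean, disjoint and sized as configured", {
  m <- make_roi_masks(c(10, 10, 10), informative_side = 3)
  expect_true(all(m$full))
  expect_equal(sum(m$informative), 27)
  expect_equal(sum(m$informative & m$uninformative), 0)
  expect_equal(sum(m$granular_like & m$dysgranular_like), 0)
  expect_true(all(m$granular_like | m$dysgranular_like))
})

test_that("condition label mapping is fixed and bijective", {
  tab <- flavour_conditions()
  expect_equal(nrow(tab), 5L)
  expect_false(anyDuplicated(tab$label) > 0)
  expect_equal(condition_modality("SweO"), "odour")
  expect_equal(condition_flavour("SavT"), "savoury")
  expect_error(condition_modality("XyZ"), "unknown")
})
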