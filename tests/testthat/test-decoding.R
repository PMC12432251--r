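test_that("partition schemes produce the documented folds", {
  d1 <- tiny_dataset(seed = 1, n_sessions = 1L)
  loro <- make_partitions(d1, "LORO-taste")
  expect_equal(length(loro$folds), 6L)
  for (f in loro$folds) {
    expect_equal(length(f$test), 2L)
    expect_equal(length(f$train), 10L)
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_false(loro$centring)

  d2 <- tiny_dataset(seed = 2)
  cm <- make_partitions(d2, "crossmodal")
  expect_equal(length(cm$folds), 2L)
  expect_true(cm$centring)
  mods <- d2$meta$modality
  expect_true(all(mods[cm$folds[[1]]$train] == "taste"))
  expect_true(all(mods[cm$folds[[1]]$test] == "odour"))

  ad <- make_partitions(d2, "across-day")
  for (f in ad$folds) {
    expect_equal(length(unique(d2$meta$session[f$train])), 1L)
    expect_equal(length(unique(d2$meta$session[f$test])), 1L)
    expect_false(d2$meta$session[f$train[1]] == d2$meta$session[f$test[1]])
  }

  wd <- make_partitions(d2, "within-day")
  for (f in wd$folds)
    expect_equal(length(unique(d2$meta$session[c(f$train, f$test)])), 1L)

  l4 <- make_partitions(d2, "LORO-4class")
  expect_equal(l4$label_field, "condition")
  expect_equal(length(l4$folds), 12L)
  expect_true(all(vapply(l4$folds, function(f) length(f$test), 1L) == 4L))

  expect_error(make_partitions(d1, "across-day"),
               class = "flavdecode_missing_session")
  expect_error(make_partitions(d1, "nonsense"), "unknown scheme")
})

test_that("partition construction is reproducible", {
  d <- tiny_dataset(seed = 3)
  expect_identical(make_partitions(d, "crossmodal"),
                   make_partitions(d, "crossmodal"))
})

test_that("training-mean centring is idempotent and offset-invariant", {
  set.seed(4)
  tr <- matrix(rnorm(40), 8); te <- matrix(rnorm(20), 4)
  c1 <- center_by_training_mean(tr, te)
  shift <- sweep(tr, 2, rnorm(5, 10), "+")
  c2 <- center_by_training_mean(shift, te)
  expect_equal(c1$train, c2$train)
  c3 <- center_by_training_mean(c1$train, c1$test)
  expect_equal(c3$train, c1$train)
  expect_equal(c3$test, c1$test)
})

test_that("the linear SVM agrees with the LIBSVM reference", {
  library(e1071)
  set.seed(5)
  for (rep in 1:40) {
    n <- sample(8:26, 1); p <- sample(3:30, 1)
    X <- matrix(rnorm(n * p), n)
    y <- factor(sample(c("sweet", "savoury"), n, TRUE))
    if (length(unique(y)) < 2) next
    Xt <- matrix(rnorm(10 * p), 10)
    mine <- fit_predict_linear(X, y, Xt)
    ref <- as.character(predict(svm(X, y, kernel = "linear", cost = 1,
                                    scale = FALSE), Xt))
    expect_identical(as.character(mine), ref)
  }
  # one-vs-one multiclass
  for (rep in 1:10) {
    p <- 15
    mu <- matrix(rnorm(4 * p), 4) * 1.5
    y <- factor(rep(c("SweT", "SavT", "SweO", "SavO"), 6))
    X <- mu[as.integer(y), ] + matrix(rnorm(24 * p), 24)
    Xt <- mu[rep(1:4, 3), ] + matrix(rnorm(12 * p), 12)
    mine <- fit_predict_linear(X, y, Xt)
    ref <- as.character(predict(svm(X, y, kernel = "linear", cost = 1,
                                    scale = FALSE), Xt))
    expect_identical(as.character(mine), ref)
  }
})

test_that("linear SVM solves separable toys and ignores duplicated features", {
  X <- rbind(c(-2, 0), c(-1, 0.5), c(1, -0.5), c(2, 0))
  y <- c("a", "a", "b", "b")
  Xt <- rbind(c(-3, 0.2), c(3, -0.2))
  expect_identical(as.character(fit_predict_linear(X, y, Xt)), c("a", "b"))
  set.seed(6)
  y2 <- rep(c("a", "b"), 6)
  X2 <- matrix(rnorm(12 * 6), 12) + ifelse(y2 == "a", 2, -2)
  Xt2 <- matrix(rnorm(8 * 6), 8)
  p1 <- fit_predict_linear(X2, y2, Xt2)
  p2 <- fit_predict_linear(cbind(X2, X2), y2, cbind(Xt2, Xt2))
  expect_identical(as.character(p1), as.character(p2))
  expect_error(fit_predict_linear(X2, rep("a", 12), Xt2), "single class")
})

test_that("label shuffling drives accuracy to chance", {
  d <- tiny_dataset(seed = 7, noise = 1, amp = 0.2, n_sessions = 1L)
  accs <- within_subject_null(d, NULL, "LORO-taste", n_perm = 400, seed = 7)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("ROI decoding is perfect for fully shared noise-free patterns", {
  d <- tiny_dataset(seed = 8, alpha = 1, noise = 0)
  expect_equal(decode_roi(d, NULL, "crossmodal")$mean_acc, 1)
  expect_equal(decode_roi(d, NULL, "LORO-taste")$mean_acc, 1)
  expect_error(decode_roi(d, integer(0), "crossmodal"), "empty mask")
})

test_that("decoding results carry coherent confusion structure", {
  d <- separable_dataset(seed = 9)
  res <- decode_roi(d, NULL, "LORO-4class")
  expect_equal(res$mean_acc, 1)
  expect_equal(res$chance, 0.25)
  expect_true(all(res$confusion == diag(12)[1:4, 1:4] * 12 |
                    res$confusion == 0))
  expect_equal(sum(res$confusion), nrow(res$predictions))
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion), res$mean_acc)
})

test_that("searchlight equals ROI decoding in limiting cases", {
  g <- c(3, 3, 2)
  d <- tiny_dataset(seed = 10, alpha = 0.7, noise = 0.8, grid = g,
                    n_sessions = 1L)
  # radius larger than the grid: every sphere is the full grid
  sl <- searchlight(d, "crossmodal", radius_voxels = 10)
  roi <- decode_roi(d, NULL, "crossmodal")
  expect_true(all(abs(sl$map - (roi$mean_acc - roi$chance)) < 1e-12))
  # isolated single-voxel mask: sphere = that voxel
  mask <- rep(FALSE, prod(g)); mask[7] <- TRUE
  sl1 <- searchlight(d, "crossmodal", radius_voxels = 3, mask = mask)
  roi1 <- decode_roi(d, 7L, "crossmodal")
  expect_equal(sl1$map[!is.na(sl1$map)], roi1$mean_acc - roi1$chance)
  expect_equal(sum(!is.na(sl1$map)), 1L)
})

test_that("leave-one-subject-out ROIs are independent of the held-out subject", {
  set.seed(11)
  g <- c(10, 10, 8)
  blob <- array(FALSE, g); blob[3:7, 3:7, 3:6] <- TRUE # 100 voxels
  maps <- lapply(1:8, function(i)
    array(rnorm(prod(g), 0, 0.5), g) + blob * 4)
  roi <- loso_roi(maps, 1, p_thresh = 0.01, k_min = 20)
  expect_gte(sum(roi & blob) / sum(blob), 0.9)
  maps2 <- maps; maps2[[1]] <- array(rnorm(prod(g), 100, 50), g)
  expect_identical(loso_roi(maps2, 1, p_thresh = 0.01, k_min = 20), roi)
  # all-zero group maps give an empty mask
  zmaps <- lapply(1:6, function(i) array(0, g))
  expect_equal(sum(loso_roi(zmaps, 1, k_min = 5)), 0)
  expect_error(loso_roi(maps[1:3], 1), "3 remaining")
})

test_that("spherical confusion matrices are row-normalised with 25% chance", {
  d <- separable_dataset(seed = 12)
  res <- confusion_from_sphere(d, centre = c(2, 2, 1), radius_mm = 6)
  expect_equal(unname(rowSums(res$proportions)), rep(1, 4))
  expect_equal(res$chance, 0.25)
  expect_true(all(diag(res$proportions) == 1))
  expect_true(all(diag(res$flagged)))
  expect_error(confusion_from_sphere(d, c(100, 100, 100), 2), "empty sphere")
})
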