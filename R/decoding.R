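#' Build a train/test partition scheme over a beta dataset
#'
#' Declarative cross-validation partitions for one subject's samples:
#' \describe{
#'   \item{LORO-taste / LORO-odour}{leave-one-run-out over the runs of both
#'     sessions within one modality; labels are flavours.}
#'   \item{crossmodal}{two folds: train on all taste samples, test on all
#'     odour samples, and the reverse; mean centring on (each side centred
#'     by its own mean pattern, removing modality offsets exactly).}
#'   \item{within-day}{leave-one-run-out restricted to each session in turn
#'     (`modality` = taste/odour), or per-session crossmodal folds
#'     (`modality` = "crossmodal").}
#'   \item{across-day}{train on all runs of one session, test on the other,
#'     both directions; centring on.}
#'   \item{LORO-4class}{leave-one-run-out over the four non-control
#'     conditions; labels are condition labels.}
#' }
#'
#' @param dataset a [beta_dataset()] (single subject) or its `meta`.
#' @param scheme scheme name (see above).
#' @param modality for within-day/across-day: "taste", "odour" or
#'   "crossmodal".
#' @return list of class `partition_scheme` with `name`, `folds` (each a
#'   list with integer `train`, `test`), `label_field` ("flavour" or
#'   "condition") and `centring`.
#' @export
make_partitions <- function(dataset, scheme,
                            modality = c("taste", "odour", "crossmodal")) {
  meta <- if (inherits(dataset, "beta_dataset")) dataset$meta else dataset
  modality <- match.arg(modality)
  if (length(unique(meta$subject)) > 1L)
    stop("make_partitions expects a single subject's samples")
  if (!"modality" %in% names(meta)) meta$modality <- condition_modality(meta$condition)

  sess <- sort(unique(meta$session))
  runs_of <- function(s) sort(unique(meta$run[meta$session == s]))
  idx_mod <- function(m, s = NULL) {
    k <- meta$modality == m & meta$condition != "ArtS"
    if (!is.null(s)) k <- k & meta$session == s
    which(k)
  }
  loro_folds <- function(samples) {
    cells <- unique(meta[samples, c("session", "run")])
    lapply(seq_len(nrow(cells)), function(i) {
      te <- samples[meta$session[samples] == cells$session[i] &
                      meta$run[samples] == cells$run[i]]
      list(train = setdiff(samples, te), test = te)
    })
  }
  need_two_sessions <- function() {
    if (length(sess) < 2L)
      stop(structure(class = c("flavdecode_missing_session", "error",
                               "condition"),
                     list(message = paste0("scheme '", scheme,
                                           "' requires 2 sessions"),
                          call = NULL)))
  }

  folds <- NULL; label_field <- "flavour"; centring <- FALSE
  if (scheme == "LORO-taste") {
    folds <- loro_folds(idx_mod("taste"))
  } else if (scheme == "LORO-odour") {
    folds <- loro_folds(idx_mod("odour"))
  } else if (scheme == "crossmodal") {
    ta <- idx_mod("taste"); od <- idx_mod("odour")
    folds <- list(list(train = ta, test = od), list(train = od, test = ta))
    centring <- TRUE
  } else if (scheme == "within-day") {
    if (modality == "crossmodal") {
      centring <- TRUE
      folds <- do.call(c, lapply(sess, function(s) {
        ta <- idx_mod("taste", s); od <- idx_mod("odour", s)
        list(list(train = ta, test = od), list(train = od, test = ta))
      }))
    } else {
      folds <- do.call(c, lapply(sess, function(s)
        loro_folds(idx_mod(modality, s))))
    }
  } else if (scheme == "across-day") {
    need_two_sessions(); centring <- TRUE
    if (modality == "crossmodal") {
      folds <- do.call(c, lapply(list(c(1, 2), c(2, 1)), function(p) {
        s_tr <- sess[p[1]]; s_te <- sess[p[2]]
        list(list(train = idx_mod("taste", s_tr), test = idx_mod("odour", s_te)),
             list(train = idx_mod("odour", s_tr), test = idx_mod("taste", s_te)))
      }))
    } else {
      folds <- lapply(list(c(1, 2), c(2, 1)), function(p)
        list(train = idx_mod(modality, sess[p[1]]),
             test = idx_mod(modality, sess[p[2]])))
    }
  } else if (scheme == "LORO-4class") {
    label_field <- "condition"
    folds <- loro_folds(which(meta$condition != "ArtS"))
  } else {
    stop("unknown scheme: ", scheme)
  }

  for (f in folds)
    if (length(intersect(f$train, f$test)))
      stop("internal error: overlapping train/test fold")
  structure(list(name = scheme, folds = folds, label_field = label_field,
                 centring = centring, modality = modality),
            class = "partition_scheme")
}

#' Centre train and test data by the training mean
#'
#' Subtracts the single mean pattern of the training samples from both the
#' training and the testing data, removing mass-univariate (e.g. modality)
#' offsets before cross-classification.
#'
#' @param train,test samples x voxels matrices.
#' @return list with centred `train` and `test`.
#' @export
center_by_training_mean <- function(train, test) {
  m <- colMeans(train)
  list(train = sweep(train, 2L, m), test = sweep(test, 2L, m))
}

# one-vs-one linear C-SVC on precomputed kernel blocks: Ktt is the
# train-train Gram, Ket the test-train block. Returns predicted labels
# (plus 2-class decision values).
svm_block_predict <- function(Ktt, Ket, ytr, cost = 1,
                              allow_single_class = FALSE) {
  classes <- sort(unique(ytr))
  if (length(classes) < 2L) {
    if (allow_single_class)   # degenerate permuted fold: constant classifier
      return(list(pred = rep(classes, nrow(Ket)), decision = NULL))
    stop("training set has a single class")
  }
  n_te <- nrow(Ket)
  votes <- matrix(0L, nrow = n_te, ncol = length(classes),
                  dimnames = list(NULL, classes))
  dec <- NULL
  for (i in seq_along(classes)[-length(classes)]) {
    for (j in (i + 1L):length(classes)) {
      sel <- ytr %in% c(classes[i], classes[j])
      yy <- ifelse(ytr[sel] == classes[i], 1L, -1L)
      fit <- smo_train(Ktt[sel, sel, drop = FALSE], yy, cost)
      d <- smo_decision(Ket[, sel, drop = FALSE], fit$alpha, yy, fit$b)
      win <- ifelse(d >= 0, classes[i], classes[j])
      for (cl in classes) votes[, cl] <- votes[, cl] + (win == cl)
      if (length(classes) == 2L) dec <- d
    }
  }
  pred <- classes[max.col(votes, ties.method = "first")]
  list(pred = pred, decision = dec)
}

svm_gram_predict <- function(K, tr, te, labels, cost = 1,
                             allow_single_class = FALSE) {
  svm_block_predict(K[tr, tr, drop = FALSE], K[te, tr, drop = FALSE],
                    as.character(labels[tr]), cost, allow_single_class)
}

#' Linear support-vector classification
#'
#' Soft-margin linear maximum-margin classifier (C-SVC, default cost 1, no
#' feature scaling), multi-class via one-vs-one voting, solved by an exact
#' dual SMO on the Gram matrix. Deterministic given its inputs.
#'
#' @param train samples x voxels training matrix.
#' @param labels training labels (character or factor).
#' @param test samples x voxels test matrix.
#' @param cost soft-margin regularisation constant C.
#' @return character vector of predicted labels; for two-class problems the
#'   decision values are attached as attribute `"decision"`.
#' @export
fit_predict_linear <- function(train, labels, test, cost = 1) {
  train <- as.matrix(train); test <- as.matrix(test)
  stopifnot(ncol(train) == ncol(test), nrow(train) == length(labels))
  X <- rbind(train, test)
  K <- tcrossprod(X)
  res <- svm_gram_predict(K, seq_len(nrow(train)),
                          nrow(train) + seq_len(nrow(test)),
                          c(as.character(labels), rep(NA, nrow(test))), cost)
  out <- res$pred
  if (!is.null(res$decision)) attr(out, "decision") <- res$decision
  out
}

# Precompute per-fold kernel blocks for a scheme. Centring removes each
# side's mean pattern in kernel space: the training side is centred by the
# training mean and the test side by its own mean, which coincides with
# training-mean centring whenever the two sides share a mean and removes
# constant per-modality offsets exactly in cross-side (crossmodal) folds.
prepare_fold_grams <- function(K, scheme) {
  lapply(scheme$folds, function(f) {
    tr <- f$train; te <- f$test
    Ktt <- K[tr, tr, drop = FALSE]
    Ket <- K[te, tr, drop = FALSE]
    if (scheme$centring) {
      rm_tr <- rowMeans(K[, tr, drop = FALSE])
      rm_te <- rowMeans(K[, te, drop = FALSE])
      # (x_i - m_tr) . (x_j - m_tr) on the training block
      Ktt <- Ktt - outer(rm_tr[tr], rep(1, length(tr))) -
        outer(rep(1, length(tr)), rm_tr[tr]) + mean(K[tr, tr])
      # (x_i - m_te) . (x_j - m_tr) on the test-vs-train block
      Ket <- Ket - outer(rep(1, length(te)), rm_te[tr]) -
        outer(rm_tr[te], rep(1, length(tr))) + mean(K[te, tr])
    }
    list(train = tr, test = te, Ktt = Ktt, Ket = Ket)
  })
}

decode_prepared <- function(prep, scheme, labels, cost = 1,
                            allow_single_class = FALSE) {
  n_fold <- length(prep)
  fold_acc <- numeric(n_fold)
  all_true <- character(0); all_pred <- character(0); fold_id <- integer(0)
  for (fi in seq_len(n_fold)) {
    f <- prep[[fi]]
    res <- svm_block_predict(f$Ktt, f$Ket, as.character(labels[f$train]),
                             cost, allow_single_class)
    truth <- as.character(labels[f$test])
    fold_acc[fi] <- mean(res$pred == truth)
    all_true <- c(all_true, truth); all_pred <- c(all_pred, res$pred)
    fold_id <- c(fold_id, rep(fi, length(f$test)))
  }
  lev <- sort(unique(c(all_true, all_pred)))
  conf <- table(factor(all_true, lev), factor(all_pred, lev))
  chance <- 1 / length(unique(all_true))
  structure(list(scheme = scheme$name, fold_acc = fold_acc,
                 mean_acc = mean(fold_acc),
                 predictions = data.frame(fold = fold_id, true = all_true,
                                          predicted = all_pred,
                                          stringsAsFactors = FALSE),
                 confusion = conf, chance = chance),
            class = "decoding_result")
}

decode_gram <- function(K, scheme, labels, cost = 1,
                        allow_single_class = FALSE) {
  decode_prepared(prepare_fold_grams(K, scheme), scheme, labels, cost,
                  allow_single_class)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("<decoding_result> scheme:", x$scheme, "\n")
  cat(sprintf("  mean accuracy %.4f (chance %.3f) over %d folds\n",
              x$mean_acc, x$chance, length(x$fold_acc)))
  invisible(x)
}

#' Decode conditions within a region of interest
#'
#' Restricts the dataset to the in-mask voxels, applies the partition
#' scheme (with training-mean centring where the scheme requires it) and
#' reports the unweighted mean accuracy over folds together with the
#' pooled confusion matrix.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param mask logical volume/vector or voxel indices; NULL = all voxels.
#' @param scheme scheme name for [make_partitions()], or a ready
#'   `partition_scheme`.
#' @param modality passed to [make_partitions()].
#' @param cost SVM regularisation constant.
#' @return a `decoding_result`.
#' @export
decode_roi <- function(dataset, mask = NULL, scheme = "crossmodal",
                       modality = "taste", cost = 1) {
  stopifnot(inherits(dataset, "beta_dataset"))
  vox <- mask_indices(mask, ncol(dataset$values))
  if (!length(vox)) stop("decode_roi: empty mask")
  part <- if (inherits(scheme, "partition_scheme")) scheme
          else make_partitions(dataset, scheme, modality)
  X <- dataset$values[, vox, drop = FALSE]
  decode_gram(tcrossprod(X), part, dataset$meta[[part$label_field]], cost)
}

#' Searchlight decoding map
#'
#' Runs the partition scheme inside a spherical neighbourhood (closed ball
#' of `radius_voxels` in voxel units, centre included) around every in-mask
#' voxel and writes accuracy minus chance at the centre. Optionally smooths
#' the resulting map for group-level analysis.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param scheme scheme name or `partition_scheme`.
#' @param radius_voxels searchlight radius in voxel units.
#' @param mask logical volume/vector of candidate centres (and sphere
#'   members); NULL = whole grid.
#' @param modality passed to [make_partitions()].
#' @param cost SVM regularisation constant.
#' @param smooth_fwhm_mm optional Gaussian smoothing of the map (0 = none).
#' @return list of class `accuracy_map` with `map` (3D array, NA outside
#'   the mask), `chance`, `radius_voxels`.
#' @export
searchlight <- function(dataset, scheme = "crossmodal", radius_voxels = 3,
                        mask = NULL, modality = "taste", cost = 1,
                        smooth_fwhm_mm = 0) {
  stopifnot(inherits(dataset, "beta_dataset"), radius_voxels >= 1)
  grid <- dataset$grid
  V <- prod(grid)
  in_mask <- rep(FALSE, V)
  in_mask[mask_indices(mask, V)] <- TRUE
  if (!any(in_mask)) stop("searchlight: empty mask")
  part <- if (inherits(scheme, "partition_scheme")) scheme
          else make_partitions(dataset, scheme, modality)
  labels <- dataset$meta[[part$label_field]]

  r <- radius_voxels
  off <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r),
                     dz = -floor(r):floor(r))
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, , drop = FALSE]

  co <- dataset$coords
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  out <- rep(NA_real_, V)
  chance <- NA_real_
  centres <- which(in_mask)
  for (v in centres) {
    cx <- co[v, 1] + off$dx; cy <- co[v, 2] + off$dy; cz <- co[v, 3] + off$dz
    ok <- cx >= 0 & cx < nx & cy >= 0 & cy < ny & cz >= 0 & cz < nz
    lin <- cx[ok] + cy[ok] * nx + cz[ok] * nx * ny + 1L
    lin <- lin[in_mask[lin]]
    X <- dataset$values[, lin, drop = FALSE]
    res <- decode_gram(tcrossprod(X), part, labels, cost)
    if (is.na(chance)) chance <- res$chance
    out[v] <- res$mean_acc - res$chance
  }
  map <- array(out, dim = grid)
  if (smooth_fwhm_mm > 0) {
    filled <- map; filled[is.na(filled)] <- 0
    sm <- smooth_volume(filled, smooth_fwhm_mm, dataset$voxel_size_mm)
    sm[!array(in_mask, dim = grid)] <- NA
    map <- sm
  }
  structure(list(map = map, chance = chance, radius_voxels = radius_voxels),
            class = "accuracy_map")
}

#' Leave-one-subject-out functional ROI generation
#'
#' For the held-out subject, runs a voxelwise one-sample group t-test over
#' the remaining subjects' contrast (T) maps, thresholds at one-sided
#' uncorrected `p_thresh`, and keeps 6-connected clusters larger than
#' `k_min` voxels.
#'
#' @param tmaps list of per-subject 3D contrast/T maps.
#' @param subject index of the held-out subject.
#' @param p_thresh voxelwise uncorrected threshold.
#' @param k_min cluster-cutting threshold (clusters kept if size > k_min).
#' @return logical array: the held-out subject's ROI mask.
#' @export
loso_roi <- function(tmaps, subject, p_thresh = 0.01, k_min = 150) {
  stopifnot(subject >= 1L, subject <= length(tmaps))
  others <- tmaps[-subject]
  n <- length(others)
  if (n < 3L) stop("loso_roi: need at least 3 remaining subjects")
  dims <- dim(tmaps[[1L]])
  M <- vapply(others, as.numeric, numeric(prod(dims)))
  m <- rowMeans(M)
  s <- apply(M, 1L, sd)
  tv <- ifelse(s > 0, m / (s / sqrt(n)), 0)
  thr <- qt(1 - p_thresh, df = n - 1L)
  lab <- label_components(as.numeric(tv > thr), as.integer(dims), 0.5)
  keep <- which(tabulate(lab) > k_min)
  array(lab %in% keep, dim = dims)
}

#' Four-class confusion matrix from a spherical ROI
#'
#' Decodes the four non-control conditions with leave-one-run-out folds
#' inside a sphere of physical radius `radius_mm` around a centre voxel,
#' and reports the row-normalised confusion proportions; cells above the
#' 4-class chance level of 0.25 are flagged.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param centre length-3 voxel coordinates (0-based grid indices).
#' @param radius_mm sphere radius in millimetres.
#' @param cost SVM regularisation constant.
#' @return a `decoding_result` with added `proportions` (row-normalised
#'   confusion) and `flagged` (proportions > 0.25).
#' @export
confusion_from_sphere <- function(dataset, centre, radius_mm = 10, cost = 1) {
  stopifnot(inherits(dataset, "beta_dataset"), length(centre) == 3L)
  d_mm <- sqrt(colSums((t(dataset$coords) - as.numeric(centre))^2)) *
    dataset$voxel_size_mm
  vox <- which(d_mm <= radius_mm)
  if (!length(vox)) stop("confusion_from_sphere: empty sphere")
  res <- decode_roi(dataset, vox, scheme = "LORO-4class", cost = cost)
  prop <- sweep(res$confusion, 1L, pmax(rowSums(res$confusion), 1L), "/")
  res$proportions <- prop
  res$flagged <- prop > 0.25
  res
}
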