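#' Within-subject permutation null for ROI decoding
#'
#' Builds the per-subject half of the hierarchical permutation null: the
#' condition labels of the scheme's samples are shuffled within each
#' (session, run, modality) cell and the full partition scheme is re-run,
#' yielding one permuted accuracy per permutation. Fold membership is fixed
#' by the true metadata; only the labels move. Shuffling within modality as
#' well as run keeps the permuted designs balanced and the train- and
#' test-side labels of crossmodal folds independent, so run-shared signal
#' components (drift) cannot bias the null below chance.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param mask voxel mask (as in [decode_roi()]).
#' @param scheme scheme name or `partition_scheme`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param modality,cost passed through to the decoder.
#' @return numeric vector of `n_perm` permuted accuracies.
#' @export
within_subject_null <- function(dataset, mask = NULL, scheme = "crossmodal",
                                n_perm = 1000L, seed = NULL,
                                modality = "taste", cost = 1) {
  stopifnot(inherits(dataset, "beta_dataset"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  vox <- mask_indices(mask, ncol(dataset$values))
  if (!length(vox)) stop("within_subject_null: empty mask")
  part <- if (inherits(scheme, "partition_scheme")) scheme
          else make_partitions(dataset, scheme, modality)
  X <- dataset$values[, vox, drop = FALSE]
  K <- tcrossprod(X)
  prep <- prepare_fold_grams(K, part)
  labels <- dataset$meta[[part$label_field]]
  universe <- sort(unique(unlist(lapply(part$folds, function(f)
    c(f$train, f$test)))))
  cell <- interaction(dataset$meta$session[universe],
                      dataset$meta$run[universe],
                      dataset$meta$modality[universe], drop = TRUE)
  with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      perm <- labels
      for (cl in levels(cell)) {
        pos <- universe[cell == cl]
        perm[pos] <- perm[pos][sample.int(length(pos))]
      }
      decode_prepared(prep, part, perm, cost,
                      allow_single_class = TRUE)$mean_acc
    }, numeric(1))
  })
}

#' Group-level permutation p from per-subject nulls
#'
#' Resamples the group null: `n_samples` times, one permuted accuracy is
#' drawn per subject (uniformly, with replacement) and the group mean is
#' recorded. The one-tailed p is the fraction of group-null means at or
#' above the observed group mean.
#'
#' @param subject_nulls matrix (subjects x permutations) or list of
#'   per-subject null accuracy vectors.
#' @param observed_mean observed group mean accuracy.
#' @param n_samples number of group resamples.
#' @param seed integer RNG seed.
#' @param add_one if TRUE, report `(b + 1) / (N + 1)` instead of the raw
#'   ratio, guaranteeing p > 0.
#' @return list of class `null_distribution` with `group_null`, `observed`,
#'   `p`, `resolution` (1 / n_samples) and the subject nulls.
#' @export
group_null_p <- function(subject_nulls, observed_mean, n_samples = 1e5,
                         seed = NULL, add_one = FALSE) {
  if (is.list(subject_nulls))
    subject_nulls <- do.call(rbind, subject_nulls)
  subject_nulls <- as.matrix(subject_nulls)
  if (!nrow(subject_nulls) || !ncol(subject_nulls))
    stop("group_null_p: empty subject nulls")
  n_subj <- nrow(subject_nulls); n_perm <- ncol(subject_nulls)
  with_seed(seed, {
    idx <- matrix(sample.int(n_perm, n_subj * n_samples, replace = TRUE),
                  nrow = n_subj)
    draws <- matrix(subject_nulls[cbind(rep(seq_len(n_subj), n_samples),
                                        as.vector(idx))],
                    nrow = n_subj)
    group_null <- colMeans(draws)
    b <- sum(group_null >= observed_mean)
    p <- if (add_one) (b + 1) / (n_samples + 1) else b / n_samples
    structure(list(subject_nulls = subject_nulls, group_null = group_null,
                   observed = observed_mean, p = p,
                   resolution = 1 / n_samples, n_samples = n_samples),
              class = "null_distribution")
  })
}

#' Permutation-based paired t-test with repeated-measures effect size
#'
#' Paired t on the differences with a sign-flip permutation null
#' (two-tailed), plus the repeated-measures Cohen's d:
#' `d_rm = mean(diff) / sqrt(s1^2 + s2^2 - 2 r s1 s2) * sqrt(2 (1 - r))`,
#' where `r` is the cross-condition correlation. Degenerate inputs
#' (zero-variance differences) are handled explicitly: identical inputs
#' give t = 0, p = 1, d_rm = 0; a pure constant shift reports the
#' resolution bound `1 / n_perm`.
#'
#' @param a,b paired numeric vectors.
#' @param n_perm number of sign-flip permutations.
#' @param seed integer RNG seed.
#' @return list of class `effect_size` with `t`, `df`, `p`, `d_rm`,
#'   `mean_diff`, `ci` (95% CI of the mean difference), `null_t`.
#' @export
perm_paired_ttest <- function(a, b, n_perm = 1e4, seed = NULL) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  md <- mean(d); sdd <- sd(d)
  r <- suppressWarnings(cor(a, b))
  s1 <- sd(a); s2 <- sd(b)
  denom <- sqrt(max(s1^2 + s2^2 - 2 * r * s1 * s2, 0))
  d_rm <- if (md == 0) 0
          else if (is.finite(denom) && denom > 0)
            md / denom * sqrt(2 * (1 - r)) else NA_real_
  if (sdd == 0) {
    if (md == 0)
      return(structure(list(t = 0, df = n - 1L, p = 1, d_rm = 0,
                            mean_diff = 0, ci = c(0, 0), null_t = NULL),
                       class = "effect_size"))
    return(structure(list(t = sign(md) * Inf, df = n - 1L, p = 1 / n_perm,
                          d_rm = d_rm, mean_diff = md, ci = c(md, md),
                          null_t = NULL),
                     class = "effect_size"))
  }
  tval <- md / (sdd / sqrt(n))
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    dperm <- d * signs
    mp <- colMeans(dperm)
    sp <- sqrt((colSums(dperm^2) - n * mp^2) / (n - 1))
    tn <- mp / (sp / sqrt(n))
    tn[!is.finite(tn)] <- 0
    p <- mean(abs(tn) >= abs(tval))
    if (p == 0) p <- 1 / n_perm
    ci <- md + c(-1, 1) * qt(0.975, n - 1L) * sdd / sqrt(n)
    structure(list(t = tval, df = n - 1L, p = p, d_rm = d_rm,
                   mean_diff = md, ci = ci, null_t = tn),
              class = "effect_size")
  })
}

#' Pearson correlation test
#'
#' Pearson r with the classical t-based two-tailed p; degenerate
#' (zero-variance) inputs return NA with a warning.
#'
#' @param x,y numeric vectors.
#' @return list with `r`, `p`, `ci`, `n`.
#' @export
corr_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0) {
    warning("corr_test: zero variance input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = length(x))
}

#' Minimum correct responses for a one-tailed binomial criterion
#'
#' Smallest k such that `P(X >= k | n, p0) < alpha` under the binomial law;
#' used e.g. to fix the triangle-test criterion for odorant tastelessness
#' (6 of 8 at guess rate 1/3, alpha .05).
#'
#' @param n number of trials.
#' @param p0 success probability under the null.
#' @param alpha one-tailed significance level in (0, 1).
#' @return integer k, or NA with a warning if even k = n does not reach
#'   significance.
#' @export
binomial_threshold <- function(n, p0, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  stopifnot(n >= 1, p0 > 0, p0 < 1)
  tail <- pbinom((0:n) - 1, n, p0, lower.tail = FALSE)  # P(X >= k)
  ok <- which(tail < alpha)
  if (!length(ok)) {
    warning("no k in 0..n reaches significance")
    return(NA_integer_)
  }
  as.integer(ok[1L] - 1L)
}
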