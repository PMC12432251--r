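#' Per-condition T-map from run-wise betas
#'
#' One-sample t across a subject's run-wise betas for one condition, the
#' beta-level analogue of a first-level condition T-map. As in a GLM
#' T-map, the denominator is a per-voxel noise estimate shared across
#' conditions (the within-condition SD pooled over `pool_conditions`), so
#' differences of two condition T-maps cancel baseline and modality
#' offsets exactly.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param condition condition label.
#' @param pool_conditions conditions over which the within-condition
#'   variance is pooled (default: the four flavour conditions).
#' @return 3D array of t values (0 where the pooled SD is 0).
#' @export
condition_tmap_from_betas <- function(dataset, condition,
                                      pool_conditions = c("SweT", "SavT",
                                                          "SweO", "SavO")) {
  stopifnot(inherits(dataset, "beta_dataset"))
  idx <- which(dataset$meta$condition == condition)
  if (length(idx) < 2L) stop("need >= 2 samples of condition ", condition)
  m <- colMeans(dataset$values[idx, , drop = FALSE])
  ssq <- 0; df <- 0L
  for (pc in union(condition, pool_conditions)) {
    pidx <- which(dataset$meta$condition == pc)
    if (length(pidx) < 2L) next
    Xc <- dataset$values[pidx, , drop = FALSE]
    ssq <- ssq + colSums(sweep(Xc, 2L, colMeans(Xc))^2)
    df <- df + length(pidx) - 1L
  }
  s <- sqrt(ssq / df)
  tv <- ifelse(s > 0, m / (s / sqrt(length(idx))), 0)
  array(tv, dim = dataset$grid)
}

#' Voxelwise tuning-index map for one modality
#'
#' The savoury-minus-sweet T difference per voxel, which cancels
#' modality-specific mass-univariate activation and leaves the voxel's
#' flavour preference.
#'
#' @param t_savoury,t_sweet 3D T-maps of the modality's savoury and sweet
#'   conditions.
#' @param mask optional logical volume; out-of-mask voxels are set to NA.
#' @return 3D array of tuning indices.
#' @export
tuning_index_map <- function(t_savoury, t_sweet, mask = NULL) {
  stopifnot(identical(dim(t_savoury), dim(t_sweet)))
  out <- t_savoury - t_sweet
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Crossmodal tuning-index overlap
#'
#' Pearson correlation between a subject's taste and odour tuning-index
#' maps over in-mask voxels; the overlap statistic whose across-subject
#' relation to crossmodal decoding accuracy is the tuning analysis'
#' endpoint.
#'
#' @param tuning_taste,tuning_odour 3D tuning maps.
#' @param mask optional logical volume.
#' @return Pearson r.
#' @export
tuning_overlap <- function(tuning_taste, tuning_odour, mask = NULL) {
  stopifnot(identical(dim(tuning_taste), dim(tuning_odour)))
  a <- as.numeric(tuning_taste); b <- as.numeric(tuning_odour)
  keep <- if (is.null(mask)) rep(TRUE, length(a)) else as.logical(mask)
  keep <- keep & is.finite(a) & is.finite(b)
  if (sum(keep) < 3L) stop("tuning_overlap: fewer than 3 usable voxels")
  cor(a[keep], b[keep])
}

#' Subject-level tuning overlap from a beta dataset
#'
#' Convenience wrapper building the four condition T-maps from run-wise
#' betas, forming both modality tuning maps and returning their overlap.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param mask optional logical volume.
#' @return Pearson r.
#' @export
subject_tuning_overlap <- function(dataset, mask = NULL) {
  tt <- tuning_index_map(condition_tmap_from_betas(dataset, "SavT"),
                         condition_tmap_from_betas(dataset, "SweT"), mask)
  to <- tuning_index_map(condition_tmap_from_betas(dataset, "SavO"),
                         condition_tmap_from_betas(dataset, "SweO"), mask)
  tuning_overlap(tt, to, mask)
}

#' Across-subject overlap-accuracy relation
#'
#' Pearson correlation (with two-tailed p) between per-subject tuning
#' overlap values and per-subject crossmodal decoding accuracies.
#'
#' @param overlaps,accuracies numeric vectors, one value per subject.
#' @return list with `r`, `p`, `ci`, `n` (see [corr_test()]).
#' @export
overlap_vs_accuracy <- function(overlaps, accuracies) {
  corr_test(overlaps, accuracies)
}
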