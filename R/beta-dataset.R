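#' Construct a beta dataset
#'
#' The central currency of the decoding, tuning and drift analyses: a
#' samples-by-voxels matrix of run-wise GLM betas with complete per-sample
#' metadata and the voxel grid geometry.
#'
#' @param values numeric matrix, samples x voxels.
#' @param meta data frame with columns `subject`, `session`, `run`,
#'   `condition`; one row per sample, `(subject, session, run, condition)`
#'   keys unique.
#' @param grid integer length-3 voxel grid; `prod(grid)` must equal
#'   `ncol(values)`.
#' @param voxel_size_mm isotropic voxel size in millimetres.
#' @return object of class `beta_dataset`.
#' @export
beta_dataset <- function(values, meta, grid, voxel_size_mm = 2) {
  values <- as.matrix(values)
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, prod(grid) == ncol(values),
            nrow(meta) == nrow(values),
            all(c("subject", "session", "run", "condition") %in% names(meta)))
  if (!all(is.finite(values))) stop("beta values must be finite")
  key <- interaction(meta$subject, meta$session, meta$run, meta$condition,
                     drop = TRUE)
  if (anyDuplicated(key)) stop("duplicated (subject, session, run, condition) keys")
  meta$modality <- condition_modality(meta$condition)
  meta$flavour <- condition_flavour(meta$condition)
  structure(list(values = values, meta = meta, grid = grid,
                 coords = grid_coords(grid), voxel_size_mm = voxel_size_mm),
            class = "beta_dataset")
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat("<beta_dataset> ", nrow(x$values), " samples x ", ncol(x$values),
      " voxels (grid ", paste(x$grid, collapse = "x"), ")\n", sep = "")
  cat("  subjects:", paste(unique(x$meta$subject), collapse = ", "), "\n")
  cat("  sessions:", paste(sort(unique(x$meta$session)), collapse = ", "),
      " runs/session:", length(unique(x$meta$run)), "\n")
  invisible(x)
}

#' Subset a beta dataset by samples
#' @param dataset a [beta_dataset()].
#' @param idx integer or logical sample index.
#' @return a `beta_dataset` with the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "beta_dataset"))
  out <- dataset
  out$values <- dataset$values[idx, , drop = FALSE]
  out$meta <- dataset$meta[idx, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}
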