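#' @useDynLib flavdecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd cor cor.test qt qnorm pt pbinom dgamma
#'   coef confint vcov
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integer voxel coordinates of a 3D grid
#'
#' Enumerates all voxels of a grid in column-major (array) order as 0-based
#' integer coordinates, the coordinate convention used throughout for beta
#' datasets and searchlight geometry.
#'
#' @param dim integer length-3 grid dimensions.
#' @return integer matrix with `prod(dim)` rows and columns `x`, `y`, `z`.
#' @export
grid_coords <- function(dim) {
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  g <- expand.grid(x = seq_len(dim[1]) - 1L,
                   y = seq_len(dim[2]) - 1L,
                   z = seq_len(dim[3]) - 1L)
  as.matrix(g)
}

#' Deterministic fan-out of one seed into per-stage child seeds
#'
#' `child = (seed * 1009 + ordinal) mod (2^31 - 1)`, kept in integer
#' range, so one global seed reproducibly drives every stage and subject
#' of a pipeline without reusing streams.
#'
#' @param seed integer master seed.
#' @param ordinal integer stage/subject ordinal.
#' @return integer child seed.
#' @export
child_seed <- function(seed, ordinal) {
  as.integer((as.double(seed) * 1009 + ordinal) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# silently coerce a logical mask (array or vector) to voxel indices over a grid
mask_indices <- function(mask, n_voxels) {
  if (is.null(mask)) return(seq_len(n_voxels))
  if (is.logical(mask)) {
    stopifnot(length(mask) == n_voxels)
    which(mask)
  } else {
    idx <- as.integer(mask)
    stopifnot(all(idx >= 1L), all(idx <= n_voxels))
    idx
  }
}
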