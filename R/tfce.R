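#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' `TFCE(v) = sum_h e(h, v)^E * h^H * dh` over `h = dh, 2dh, ... <= max`,
#' where `e(h, v)` is the extent of the 6-connected component containing
#' `v` at height `h`. Only the positive part of the map is enhanced; an
#' all-zero (or non-positive) map returns zero everywhere.
#'
#' @param stat_map 3D numeric array.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; NULL uses `max(stat_map) / nsteps`.
#' @param nsteps number of integration steps when `dh` is NULL.
#' @return list of class `tfce_map` with `values` (array), `E`, `H`, `dh`.
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, nsteps = 100L) {
  stopifnot(length(dim(stat_map)) == 3L, E >= 0, H >= 0)
  if (!all(is.finite(stat_map))) stop("tfce: non-finite map values")
  if (!is.null(dh) && dh <= 0) stop("tfce: dh must be > 0")
  vals <- tfce_enhance(as.numeric(stat_map), as.integer(dim(stat_map)),
                       E, H, dh %||% -1, as.integer(nsteps))
  mx <- max(stat_map)
  structure(list(values = array(vals, dim = dim(stat_map)), E = E, H = H,
                 dh = dh %||% (if (mx > 0) mx / nsteps else NA_real_)),
            class = "tfce_map")
}

# signed enhancement: TFCE of the positive part minus TFCE of the negative
# part, so that negating the input negates the enhanced map
tfce_signed <- function(stat_map, E = 0.5, H = 2, nsteps = 100L) {
  pos <- pmax(stat_map, 0); neg <- pmax(-stat_map, 0)
  tfce(array(pos, dim(stat_map)), E, H, nsteps = nsteps)$values -
    tfce(array(neg, dim(stat_map)), E, H, nsteps = nsteps)$values
}

#' Group-level TFCE permutation test on accuracy maps
#'
#' Sign-flip max-statistic test over subjects' chance-subtracted accuracy
#' maps: the observed group mean map is TFCE-enhanced (signed), a null of
#' maximal absolute enhanced statistics is built from random sign flips of
#' the subject maps, voxelwise p-values against that null are converted to
#' signed z-scores, and survivors are 6-connected clusters of more than
#' `k_min` voxels exceeding `z_thresh` (one-tailed).
#'
#' @param maps list of per-subject 3D maps (accuracy minus chance).
#' @param n_sims number of sign-flip Monte-Carlo simulations.
#' @param seed integer RNG seed.
#' @param E,H,nsteps TFCE parameters.
#' @param z_thresh one-tailed z threshold for survivors.
#' @param k_min cluster extent threshold (clusters kept if size > k_min).
#' @return list of class `tfce_test` with `z` (array), `tfce_obs`,
#'   `null_max`, `survivors` (logical array), `params`.
#' @export
group_tfce_test <- function(maps, n_sims = 1000L, seed = NULL, E = 0.5,
                            H = 2, nsteps = 100L, z_thresh = 1.65,
                            k_min = 15L) {
  n <- length(maps)
  if (n < 3L) stop("group_tfce_test: need at least 3 subjects")
  dims <- dim(maps[[1L]])
  M <- vapply(maps, as.numeric, numeric(prod(dims)))
  obs_mean <- array(rowMeans(M), dims)
  enh_obs <- tfce_signed(obs_mean, E, H, nsteps)
  with_seed(seed, {
    null_max <- vapply(seq_len(n_sims), function(s) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      m <- array(as.vector(M %*% signs) / n, dims)
      max(abs(tfce_signed(m, E, H, nsteps)))
    }, numeric(1))
    pv <- (1 + vapply(abs(enh_obs), function(v) sum(null_max >= v),
                      numeric(1))) / (n_sims + 1)
    # two-sided p against the max-|statistic| null, converted to a signed z
    # (one-sided threshold z > 1.65 then corresponds to one-tailed p < .05)
    z <- sign(enh_obs) * qnorm(1 - pv / 2)
    z <- array(z, dims)
    lab <- label_components(as.numeric(z > z_thresh), as.integer(dims), 0.5)
    keep <- which(tabulate(lab) > k_min)
    surv <- array(lab %in% keep, dims)
    structure(list(z = z, tfce_obs = array(enh_obs, dims),
                   null_max = null_max, survivors = surv,
                   params = list(E = E, H = H, nsteps = nsteps,
                                 z_thresh = z_thresh, k_min = k_min,
                                 n_sims = n_sims)),
              class = "tfce_test")
  })
}
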