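#' End-to-end pipeline configuration
#'
#' One plain list (YAML-serialisable, lossless round trip) controlling the
#' synthetic cohort, the decoding schemes and the inference budgets of
#' [run_pipeline()].
#'
#' @param n_subjects cohort size.
#' @param grid voxel grid of the synthetic volumes.
#' @param alpha crossmodal overlap weight (scalar, or vector recycled over
#'   subjects).
#' @param sigma_noise,sigma_drift,rho_session generator parameters, see
#'   [synth_config()].
#' @param n_runs,n_sessions runs per session and number of sessions.
#' @param schemes decoding schemes to run per subject.
#' @param n_perm within-subject permutations per subject.
#' @param n_samples group-null resamples.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 8L, grid = c(16L, 16L, 16L),
                            alpha = 0.5, sigma_noise = 0.6,
                            sigma_drift = c(0.25, 0.1), rho_session = 0.7,
                            n_runs = 6L, n_sessions = 2L,
                            schemes = c("LORO-taste", "LORO-odour",
                                        "crossmodal"),
                            n_perm = 200L, n_samples = 1e4) {
  structure(list(n_subjects = as.integer(n_subjects), grid = as.integer(grid),
                 alpha = alpha, sigma_noise = sigma_noise,
                 sigma_drift = sigma_drift, rho_session = rho_session,
                 n_runs = as.integer(n_runs), n_sessions = as.integer(n_sessions),
                 schemes = schemes, n_perm = as.integer(n_perm),
                 n_samples = as.integer(n_samples)),
            class = "pipeline_config")
}

#' Write/read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return the path (write) or the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

stage_done <- function(outdir, stage, hash, seed) {
  f <- file.path(outdir, paste0("provenance_", stage, ".json"))
  if (!file.exists(f)) return(FALSE)
  p <- jsonlite::read_json(f, simplifyVector = TRUE)
  identical(p$config_hash, hash) && identical(as.integer(p$seed),
                                              as.integer(seed))
}

mark_stage <- function(outdir, stage, hash, seed) {
  jsonlite::write_json(list(stage = stage, config_hash = hash, seed = seed,
                            package_version = as.character(
                              utils::packageVersion("flavdecode"))),
                       file.path(outdir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate a cohort, decode it under the configured schemes, run the
#' hierarchical permutation inference on the crossmodal accuracies,
#' compute tuning-index overlaps and their relation to crossmodal
#' accuracy, and fit the representational-drift mixed model. Every stage
#' writes its tables plus a provenance sidecar (config hash, seed); with
#' `resume = TRUE`, stages whose provenance matches are skipped and their
#' outputs re-read.
#'
#' @param config a [pipeline_config()].
#' @param seed global seed; per-stage child seeds are derived
#'   deterministically from it.
#' @param outdir output directory.
#' @param resume skip stages with matching provenance.
#' @return list with per-stage results (`cohort` sizes, `decoding` table,
#'   `inference`, `tuning`, `drift`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         outdir = tempfile("flavpipe"), resume = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  scfg <- synth_config(grid = config$grid, alpha = config$alpha[1L],
                       sigma_noise = config$sigma_noise,
                       sigma_drift = config$sigma_drift,
                       rho_session = config$rho_session)

  # stage 1: simulate ------------------------------------------------------
  cohort <- simulate_cohort(config$n_subjects, scfg,
                            seed = child_seed(seed, 1L),
                            alpha = if (length(config$alpha) > 1L)
                              config$alpha else NULL,
                            n_runs = config$n_runs,
                            n_sessions = config$n_sessions)
  ratings <- simulate_ratings(config$n_subjects,
                              seed = child_seed(seed, 10L))
  if (!stage_done(outdir, "simulate", hash, seed)) {
    write.csv(ratings, file.path(outdir, "ratings.csv"), row.names = FALSE)
    mark_stage(outdir, "simulate", hash, seed)
  }

  # stage 2: decode --------------------------------------------------------
  dec_path <- file.path(outdir, "decoding.csv")
  if (resume && stage_done(outdir, "decode", hash, seed) &&
      file.exists(dec_path)) {
    dec <- read.csv(dec_path, stringsAsFactors = FALSE)
  } else {
    rows <- list()
    for (i in seq_along(cohort)) {
      for (sc in config$schemes) {
        res <- decode_roi(cohort[[i]], NULL, sc)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, scheme = sc, accuracy = res$mean_acc,
          chance = res$chance, stringsAsFactors = FALSE)
      }
    }
    dec <- do.call(rbind, rows)
    write.csv(dec, dec_path, row.names = FALSE)
    mark_stage(outdir, "decode", hash, seed)
  }

  # stage 3: inference (crossmodal group p) --------------------------------
  inf_path <- file.path(outdir, "inference.json")
  if (resume && stage_done(outdir, "infer", hash, seed) &&
      file.exists(inf_path)) {
    inference <- jsonlite::read_json(inf_path, simplifyVector = TRUE)
  } else {
    inference <- list()
    for (sc in intersect(config$schemes, c("crossmodal", "LORO-taste",
                                           "LORO-odour"))) {
      nulls <- t(vapply(seq_along(cohort), function(i)
        within_subject_null(cohort[[i]], NULL, sc, config$n_perm,
                            seed = child_seed(seed, 100L + i)),
        numeric(config$n_perm)))
      obs <- mean(dec$accuracy[dec$scheme == sc])
      nd <- group_null_p(nulls, obs, config$n_samples,
                         seed = child_seed(seed, 200L))
      inference[[sc]] <- list(observed = obs, p = nd$p,
                              null_mean = mean(nd$group_null))
    }
    jsonlite::write_json(inference, inf_path, auto_unbox = TRUE, digits = NA)
    mark_stage(outdir, "infer", hash, seed)
  }

  # stage 4: tuning overlap ------------------------------------------------
  tun_path <- file.path(outdir, "tuning.csv")
  if (resume && stage_done(outdir, "tuning", hash, seed) &&
      file.exists(tun_path)) {
    tun <- read.csv(tun_path, stringsAsFactors = FALSE)
  } else {
    overlaps <- vapply(cohort, subject_tuning_overlap, numeric(1))
    acc_cm <- dec$accuracy[dec$scheme == "crossmodal"]
    tun <- data.frame(subject = seq_along(cohort), overlap_r = overlaps,
                      crossmodal_accuracy = acc_cm)
    write.csv(tun, tun_path, row.names = FALSE)
    mark_stage(outdir, "tuning", hash, seed)
  }
  tun_rel <- overlap_vs_accuracy(tun$overlap_r, tun$crossmodal_accuracy)

  # stage 5: drift ---------------------------------------------------------
  drift_path <- file.path(outdir, "drift_table.csv")
  if (resume && stage_done(outdir, "drift", hash, seed) &&
      file.exists(drift_path)) {
    dtab <- read.csv(drift_path, stringsAsFactors = FALSE)
  } else {
    dtab <- drift_table_cohort(cohort)
    write.csv(dtab, drift_path, row.names = FALSE)
    mark_stage(outdir, "drift", hash, seed)
  }
  drift_fit <- fit_drift_lmm(dtab)
  jsonlite::write_json(drift_fit$fixed, file.path(outdir, "drift_lmm.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  list(outdir = outdir, cohort_size = length(cohort), decoding = dec,
       inference = inference, tuning = tun, tuning_relation = tun_rel,
       drift_table = dtab, drift_fit = drift_fit, ratings = ratings)
}
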