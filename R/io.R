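#' Write an event schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`, `event_class`, `run`,
#' `session`, tab-separated.
#'
#' @param schedule an [make_design_events()] schedule.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "event_schedule"))
  ev <- schedule$events
  ev$run <- schedule$run_id
  ev$session <- schedule$session_id
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path input path.
#' @param run_length_s run length to record on the schedule; defaults to
#'   the last event offset.
#' @return an `event_schedule`.
#' @export
read_events_tsv <- function(path, run_length_s = NULL) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  run_id <- ev$run[1L] %||% 1L
  session_id <- ev$session[1L] %||% 1L
  ev$run <- NULL; ev$session <- NULL
  structure(list(events = ev, run_id = as.integer(run_id),
                 session_id = as.integer(session_id),
                 run_length_s = run_length_s %||% max(ev$onset + ev$duration)),
            class = "event_schedule")
}

#' Write/read a motion-parameter table as 6-column TSV
#' @param motion frames x 6 matrix.
#' @param path file path.
#' @return the path (write) or the motion matrix (read).
#' @export
write_motion_tsv <- function(motion, path) {
  stopifnot(ncol(motion) == 6L)
  write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("tx", "ty", "tz", "rx", "ry", "rz"))
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  as.matrix(read.delim(path))
}

#' Write a 3D/4D array as NIfTI-1
#'
#' @param volume numeric array (3D volume or 4D series; logical masks are
#'   stored as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm isotropic voxel size recorded in the header.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(volume * 1,
                         pixdim = rep(voxel_size_mm,
                                      min(3L, length(dim(volume)))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#' @param path input path.
#' @return numeric array.
#' @export
read_volume_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' Write a beta dataset as per-sample NIfTI images plus a manifest
#'
#' Files are named `sub-<s>_ses-<n>_run-<r>_cond-<label>_beta.nii.gz`; the
#' manifest CSV records `path`, `subject`, `session`, `run`, `condition`,
#' and a JSON sidecar stores the grid and voxel size.
#'
#' @param dataset a [beta_dataset()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_beta_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "beta_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- dataset$meta
  fn <- sprintf("sub-%02d_ses-%d_run-%d_cond-%s_beta.nii.gz",
                as.integer(factor(meta$subject)), meta$session, meta$run,
                meta$condition)
  for (i in seq_len(nrow(meta)))
    write_volume_nifti(array(dataset$values[i, ], dim = dataset$grid),
                       file.path(dir, fn[i]), dataset$voxel_size_mm)
  man <- data.frame(path = fn, subject = meta$subject,
                    session = meta$session, run = meta$run,
                    condition = meta$condition, stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.csv")
  write.csv(man, man_path, row.names = FALSE)
  jsonlite::write_json(list(grid = dataset$grid,
                            voxel_size_mm = dataset$voxel_size_mm),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(man_path)
}

#' Read a beta dataset from a manifest written by [write_beta_dataset()]
#'
#' @param manifest_path path of the manifest CSV.
#' @return a [beta_dataset()].
#' @export
read_beta_dataset <- function(manifest_path) {
  dir <- dirname(manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  values <- t(vapply(man$path, function(p)
    as.numeric(read_volume_nifti(file.path(dir, p))),
    numeric(prod(side$grid))))
  rownames(values) <- NULL
  beta_dataset(values, man[, c("subject", "session", "run", "condition")],
               side$grid, side$voxel_size_mm)
}
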