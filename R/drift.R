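#' Correlation-distance representational dissimilarity matrix
#'
#' Pairwise dissimilarity (1 minus the voxel-voxel Pearson correlation)
#' between a subject's run-wise beta patterns of the four flavour
#' conditions, with cross-session pairs flagged for exclusion from the
#' drift analysis.
#'
#' @param dataset a single-subject [beta_dataset()].
#' @param mask optional voxel mask.
#' @param conditions conditions entering the RDM.
#' @return list of class `rdm` with `mat` (dissimilarities), `items`
#'   (per-row metadata) and `same_session` (logical matrix).
#' @export
neural_rdm <- function(dataset, mask = NULL,
                       conditions = c("SweT", "SavT", "SweO", "SavO")) {
  stopifnot(inherits(dataset, "beta_dataset"))
  idx <- which(dataset$meta$condition %in% conditions)
  if (length(idx) < 2L) stop("neural_rdm: fewer than 2 items")
  vox <- mask_indices(mask, ncol(dataset$values))
  X <- dataset$values[idx, vox, drop = FALSE]
  D <- 1 - cor(t(X))
  items <- dataset$meta[idx, , drop = FALSE]
  rownames(items) <- NULL
  same <- outer(items$session, items$session, "==")
  diag(D) <- 0
  structure(list(mat = D, items = items, same_session = same),
            class = "rdm")
}

#' Scaled run-wise distances
#'
#' Pairwise absolute differences between run indices, divided by the
#' largest pairwise difference within the session, so the most distant
#' runs are 1 apart (e.g. runs 1..6: d(1, 6) = 1, d(1, 2) = 0.2).
#'
#' @param run_ids integer run indices of one session.
#' @return symmetric matrix of scaled distances.
#' @export
runwise_distance <- function(run_ids) {
  d <- abs(outer(run_ids, run_ids, "-"))
  mx <- max(d)
  if (mx > 0) d <- d / mx
  d
}

#' Assemble the long-format drift table
#'
#' One row per unordered within-session pair of (run, condition) items
#' from different runs: the neural dissimilarity, the flavour distance
#' (0 = same flavour), the modality distance (0 = same modality), the
#' scaled run distance, the session and the subject. Same-run pairs and
#' cross-session pairs are excluded.
#'
#' @param rdm a [neural_rdm()] result.
#' @return data frame of class `drift_table`.
#' @export
assemble_drift_table <- function(rdm) {
  stopifnot(inherits(rdm, "rdm"))
  it <- rdm$items
  rows <- list()
  for (s in sort(unique(it$session))) {
    in_s <- which(it$session == s)
    runs <- sort(unique(it$run[in_s]))
    rd <- runwise_distance(runs)
    dimnames(rd) <- list(runs, runs)
    n <- length(in_s)
    for (ai in seq_len(n - 1L)) {
      for (bi in (ai + 1L):n) {
        i <- in_s[ai]; j <- in_s[bi]
        if (it$run[i] == it$run[j]) next
        rows[[length(rows) + 1L]] <- data.frame(
          dissimilarity = rdm$mat[i, j],
          flavour_dist = as.integer(it$flavour[i] != it$flavour[j]),
          modality_dist = as.integer(it$modality[i] != it$modality[j]),
          run_dist = rd[as.character(it$run[i]), as.character(it$run[j])],
          session = s,
          subject = it$subject[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("drift_table", class(out))
  out
}

#' Drift tables for a cohort
#'
#' @param datasets list of per-subject [beta_dataset()] objects.
#' @param mask optional voxel mask.
#' @return row-bound `drift_table` across subjects.
#' @export
drift_table_cohort <- function(datasets, mask = NULL) {
  out <- do.call(rbind, lapply(datasets, function(d)
    assemble_drift_table(neural_rdm(d, mask))))
  rownames(out) <- NULL
  out
}

# extract a tidy fixed-effects table (Satterthwaite df) from an lmerTest fit
lmm_result <- function(fit, singular, formula_used) {
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("beta", "se", "df", "t", "p")
  ci_half <- qt(0.975, pmax(co$df, 1)) * co$se
  res <- data.frame(term = rownames(co), beta = co$beta, se = co$se,
                    t = co$t, df = co$df, p = co$p,
                    ci_lo = co$beta - ci_half, ci_hi = co$beta + ci_half,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fixed = res, logLik = as.numeric(stats::logLik(fit)),
                 singular = singular, formula = formula_used, model = fit),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> ", x$formula, "\n", sep = "")
  if (x$singular) cat("  (random-effects covariance reduced to diagonal)\n")
  print(x$fixed, digits = 4)
  invisible(x)
}

#' Fit the representational-drift linear mixed model
#'
#' Models the neural dissimilarity of within-session run pairs by
#' `flavour_dist * run_dist + flavour_dist * session + modality_dist +
#' session * run_dist`, with by-subject random intercepts and random
#' slopes for run distance, modality distance, flavour distance and
#' session. Session is coded as a centred binary covariate (-0.5 for
#' session 1, +0.5 for session 2). Fitted by maximum likelihood; on a
#' singular random-effects covariance the model is refit with a diagonal
#' (uncorrelated) random structure.
#'
#' @param table a [assemble_drift_table()] / [drift_table_cohort()] table.
#' @return an `lmm_result` with the fixed-effect estimates.
#' @export
fit_drift_lmm <- function(table) {
  stopifnot(nrow(table) > 0)
  if (length(unique(table$subject)) < 2L)
    stop("fit_drift_lmm: need >= 2 subjects")
  tab <- as.data.frame(table)
  two_sessions <- length(unique(tab$session)) > 1L
  if (two_sessions) tab$session_c <- ifelse(tab$session == min(tab$session),
                                            -0.5, 0.5)
  fml <- if (two_sessions)
    paste("dissimilarity ~ flavour_dist * run_dist + flavour_dist *",
          "session_c + modality_dist + session_c * run_dist +",
          "(1 + flavour_dist + modality_dist + session_c + run_dist | subject)")
  else
    paste("dissimilarity ~ flavour_dist * run_dist + modality_dist +",
          "(1 + flavour_dist + modality_dist + run_dist | subject)")
  fit_one <- function(f) suppressWarnings(
    lmerTest::lmer(stats::as.formula(f), data = tab, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))
  fit <- try(fit_one(fml), silent = TRUE)
  singular <- inherits(fit, "try-error") || lme4::isSingular(fit)
  if (singular) {
    fml2 <- gsub("\\|", "||", fml)
    fit2 <- try(fit_one(fml2), silent = TRUE)
    if (!inherits(fit2, "try-error")) return(lmm_result(fit2, TRUE, fml2))
    if (inherits(fit, "try-error"))
      stop("fit_drift_lmm: model failed to converge: ",
           attr(fit, "condition")$message)
  }
  lmm_result(fit, singular, fml)
}

#' Within-day versus across-day decoding comparison
#'
#' Mixed model of per-subject decoding accuracies with partition type
#' (within vs across day) as fixed effect and a by-subject random
#' intercept; the reported `partitionwithin` beta is the within-minus-
#' across accuracy difference. Subjects lacking either partition type are
#' dropped with a warning.
#'
#' @param acc_table data frame with columns `subject`, `partition`
#'   ("within"/"across"), `accuracy`.
#' @return an `lmm_result`.
#' @export
within_vs_across_day <- function(acc_table) {
  stopifnot(all(c("subject", "partition", "accuracy") %in% names(acc_table)))
  tab <- as.data.frame(acc_table)
  have_both <- tapply(tab$partition, tab$subject,
                      function(p) all(c("within", "across") %in% p))
  bad <- names(have_both)[!have_both]
  if (length(bad)) {
    warning("dropping subjects without both partition types: ",
            paste(bad, collapse = ", "))
    tab <- tab[!tab$subject %in% bad, , drop = FALSE]
  }
  if (length(unique(tab$subject)) < 2L)
    stop("within_vs_across_day: need >= 2 complete subjects")
  tab$partition <- factor(tab$partition, levels = c("across", "within"))
  fml <- "accuracy ~ partition + (1 | subject)"
  fit <- suppressWarnings(
    lmerTest::lmer(stats::as.formula(fml), data = tab, REML = FALSE))
  lmm_result(fit, lme4::isSingular(fit), fml)
}

#' Per-subject within- and across-day decoding accuracies
#'
#' Runs the within-day and across-day partition schemes for every subject
#' of a cohort; single-session subjects are skipped with a warning
#' (mirroring cohorts where one subject misses a session).
#'
#' @param datasets list of per-subject [beta_dataset()] objects.
#' @param mask optional voxel mask.
#' @param modality "taste", "odour" or "crossmodal".
#' @param cost SVM regularisation constant.
#' @return data frame with `subject`, `partition`, `accuracy`.
#' @export
decode_within_across <- function(datasets, mask = NULL, modality = "taste",
                                 cost = 1) {
  rows <- list()
  for (d in datasets) {
    subj <- d$meta$subject[1L]
    w <- decode_roi(d, mask, "within-day", modality, cost)$mean_acc
    a <- tryCatch(decode_roi(d, mask, "across-day", modality, cost)$mean_acc,
                  flavdecode_missing_session = function(e) {
                    warning("subject ", subj,
                            " has a single session; skipped", call. = FALSE)
                    NA_real_
                  })
    if (is.na(a)) next
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subj, partition = c("within", "across"),
      accuracy = c(w, a), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
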