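# End-to-end pipeline: QC gate -> predictors -> cross-validated ensemble
# scores -> interpretation and diagnostic report. Deterministic given
# (cohort, config): every random draw derives from config$seed.

#' Run the full analysis pipeline on a cohort
#'
#' Stages run in fixed order: [apply_qc()] (samples failing QC never reach
#' scoring), [predictor_matrix()], [crossval_scores()] (out-of-fold
#' miR-CERVIX per sample), then [score_category()] and
#' [diagnostic_report()]. Stage counts (enrolled, excluded with reasons,
#' scored) are logged via `message()` and returned.
#'
#' @param cohort an `mc_cohort` with NILM/HSIL diagnoses.
#' @param config an [mc_config()].
#' @return list of class `mc_result`: `scores` (data.frame `sample_id`,
#'   `mir_cervix`, `fold`, `category`, `diagnosis`, `hpv_status`), `qc`
#'   (per-sample verdicts), `report` (an `mc_report`), `model` (ensemble
#'   fitted on all passing samples, for importances), `counts`, `config`.
#' @export
run_pipeline <- function(cohort, config = mc_config()) {
  validate_cohort(cohort)
  validate_config(config)
  gate <- apply_qc(cohort, config$qc)
  passing <- gate$passing
  n_enrolled <- nrow(cohort)
  n_passing <- nrow(passing)
  message(
    "enrolled: ", n_enrolled, "; excluded by QC: ",
    n_enrolled - n_passing, "; eligible: ", n_passing
  )
  labels <- passing$diagnosis
  if (!all(labels %in% c("NILM", "HSIL"))) {
    stop("pipeline training needs NILM/HSIL diagnoses for all QC-passing samples")
  }
  if (length(unique(labels)) < 2) {
    stop("only one class present after QC; cannot train")
  }
  if (config$cv$k > n_passing) {
    stop(
      "k = ", config$cv$k, " folds exceed the ", n_passing,
      " QC-passing samples"
    )
  }
  X <- predictor_matrix(passing)
  cv_seed <- derive_seeds(config$seed, 2L)
  scores <- crossval_scores(X, labels, config, seed = cv_seed[1])
  scores$category <- as.character(score_category(
    scores$mir_cervix,
    config$interpret$screen_cutoff, config$interpret$confirm_cutoff
  ))
  scores$diagnosis <- labels
  scores$hpv_status <- passing$hpv_status
  model <- fit_forest(X, labels, config$forest, seed = cv_seed[2])
  report <- diagnostic_report(scores, config)
  message("scored: ", nrow(scores))
  structure(
    list(
      scores = scores, qc = gate$results, report = report, model = model,
      counts = list(
        enrolled = n_enrolled, excluded = n_enrolled - n_passing,
        scored = nrow(scores)
      ),
      config = config
    ),
    class = "mc_result"
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat("miR-CERVIX pipeline result\n")
  cat(sprintf(
    "  samples: %d enrolled, %d excluded by QC, %d scored\n",
    x$counts$enrolled, x$counts$excluded, x$counts$scored
  ))
  gm <- x$report$group_means
  cat(sprintf(
    "  mean score: NILM %.2f, HSIL %.2f\n",
    gm$NILM, gm$HSIL
  ))
  cat(sprintf("  AUC: %.3f\n", x$report$auc))
  ms <- x$report$screen$metrics
  mc <- x$report$confirm$metrics
  cat(sprintf(
    "  at %.2f: sensitivity %.2f%%, specificity %.2f%%\n",
    x$report$screen$cutoff, ms$sensitivity, ms$specificity
  ))
  cat(sprintf(
    "  at %.2f: sensitivity %.2f%%, specificity %.2f%%\n",
    x$report$confirm$cutoff, mc$sensitivity, mc$specificity
  ))
  cat(sprintf(
    "  Mann-Whitney NILM vs HSIL: p = %.3g\n", x$report$mann_whitney$p
  ))
  invisible(x)
}
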