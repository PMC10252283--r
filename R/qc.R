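# Control-reaction QC gate. A sample is analyzable only when both control
# reactions are acceptable and all six marker reactions produced a Ct.
# Boundary semantics deliberately differ between the two controls: ACTB
# fails only when strictly above the cut-off (Ct > 34 excluded, 34.0
# passes), while the spike-in must be strictly under its cut-off (18.5
# itself fails).

QC_REASONS <- c(
  "ACTB_HIGH", "SPIKEIN_HIGH", "MISSING_CONTROL", "MISSING_MARKER",
  "LOW_RNA", "LOW_PURITY"
)

#' Apply control-reaction quality gating to a cohort
#'
#' A sample passes iff `ct_actb` is present and `<= actb_max_ct`,
#' `ct_celmir39` is present and `< spikein_max_ct`, and all six marker Ct
#' values are present. When `enforce_wetlab_fields` is on, RNA
#' concentration and A260/280 purity are additionally required to meet
#' their minima. QC never hard-fails: every sample receives a verdict and
#' excluded samples carry all applicable reason codes.
#'
#' @param cohort an `mc_cohort`.
#' @param qc the `qc` sub-list of an [mc_config()] (or a compatible list).
#' @return list with `passing` (an `mc_cohort`, input order preserved) and
#'   `results` (data.frame: `sample_id`, `passed`, `reasons` — codes joined
#'   by ";").
#' @export
apply_qc <- function(cohort, qc = mc_config()$qc) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop("cohort is empty")
  marker_cols <- setdiff(CT_COLUMNS, CT_CONTROLS)
  reasons <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    r <- character(0)
    actb <- cohort$ct_actb[i]
    spike <- cohort$ct_celmir39[i]
    if (is.na(actb) || is.na(spike)) r <- c(r, "MISSING_CONTROL")
    if (!is.na(actb) && actb > qc$actb_max_ct) r <- c(r, "ACTB_HIGH")
    if (!is.na(spike) && spike >= qc$spikein_max_ct) r <- c(r, "SPIKEIN_HIGH")
    if (anyNA(unlist(cohort[i, marker_cols]))) r <- c(r, "MISSING_MARKER")
    if (isTRUE(qc$enforce_wetlab_fields)) {
      conc <- cohort$rna_conc[i]
      ratio <- cohort$a260_280[i]
      if (is.na(conc) || conc < qc$min_rna_conc) r <- c(r, "LOW_RNA")
      if (is.na(ratio) || ratio < qc$min_a260_280) r <- c(r, "LOW_PURITY")
    }
    reasons[[i]] <- r
  }
  passed <- lengths(reasons) == 0
  results <- data.frame(
    sample_id = cohort$sample_id,
    passed = passed,
    reasons = vapply(reasons, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  passing <- cohort[passed, , drop = FALSE]
  rownames(passing) <- NULL
  attr(passing, "provenance") <- attr(cohort, "provenance")
  class(passing) <- class(cohort)
  list(passing = passing, results = results)
}

#' Write QC verdicts to CSV
#'
#' @param results the `results` component of [apply_qc()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
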