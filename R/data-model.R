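# Shared data model: cohort container, assay column conventions, pipeline
# configuration. A cohort is a plain data.frame (class "mc_cohort") with one
# row per sample and one column per assay reaction, so base-R tooling works
# on it directly.

# Up-regulated markers (outer loop of the chi ordering) and stable or
# down-regulated references (inner loop).
CT_MARKERS <- c("ct_mir145", "ct_mir1246", "ct_mir1290")
CT_REFS <- c("ct_mir21", "ct_mir29b", "ct_mir451a")
CT_CONTROLS <- c("ct_actb", "ct_celmir39")
CT_COLUMNS <- c(
  "ct_mir21", "ct_mir29b", "ct_mir145", "ct_mir451a",
  "ct_mir1246", "ct_mir1290", CT_CONTROLS
)
WETLAB_COLUMNS <- c("rna_conc", "a260_280")
DIAGNOSIS_LEVELS <- c("NILM", "HSIL", "UNKNOWN")
HPV_LEVELS <- c("POS", "NEG", "UNKNOWN")

# Human-readable assay names, used in messages and pair labels.
ASSAY_NAMES <- c(
  ct_mir21 = "miR-21-5p", ct_mir29b = "miR-29b-3p", ct_mir145 = "miR-145-5p",
  ct_mir451a = "miR-451a-5p", ct_mir1246 = "miR-1246-5p",
  ct_mir1290 = "miR-1290-3p", ct_actb = "ACTB", ct_celmir39 = "cel-miR-39"
)

#' Construct a cohort of per-sample assay results
#'
#' A cohort holds one row per sample: the eight reaction Ct values (six
#' marker miRNAs plus the ACTB material control and the cel-miR-39 spike-in),
#' the morphological diagnosis, HPV status, and optional wet-lab QC fields.
#' Missing reactions are `NA`. Row order is preserved through every
#' pipeline stage.
#'
#' @param samples data.frame with at least a `sample_id` column; recognised
#'   columns are `sample_id`, `diagnosis` (`NILM`/`HSIL`/`UNKNOWN`),
#'   `hpv_status` (`POS`/`NEG`/`UNKNOWN`), the eight `ct_*` columns,
#'   `rna_conc` (ng/uL) and `a260_280`. Absent columns are filled with
#'   `NA`/`UNKNOWN`.
#' @param provenance free-text origin of the data (file path, generator
#'   seed, ...), stored as an attribute.
#' @return data.frame of class `mc_cohort`.
#' @export
mc_cohort <- function(samples, provenance = "") {
  stopifnot(is.data.frame(samples))
  if (!"sample_id" %in% names(samples)) {
    stop("cohort needs a 'sample_id' column")
  }
  df <- data.frame(sample_id = as.character(samples$sample_id))
  df$diagnosis <- if ("diagnosis" %in% names(samples)) {
    as.character(samples$diagnosis)
  } else {
    "UNKNOWN"
  }
  df$hpv_status <- if ("hpv_status" %in% names(samples)) {
    as.character(samples$hpv_status)
  } else {
    "UNKNOWN"
  }
  for (col in c(CT_COLUMNS, WETLAB_COLUMNS)) {
    df[[col]] <- if (col %in% names(samples)) {
      as.numeric(samples[[col]])
    } else {
      NA_real_
    }
  }
  rownames(df) <- NULL
  out <- structure(df, class = c("mc_cohort", "data.frame"))
  attr(out, "provenance") <- provenance
  validate_cohort(out)
  out
}

#' Validate a cohort
#'
#' Checks the container invariants: non-empty unique sample ids, recognised
#' diagnosis/HPV levels, and every present Ct value inside the plausible
#' qPCR window (0, 45].
#'
#' @param cohort an `mc_cohort`.
#' @return the cohort, invisibly; stops on violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  ids <- cohort$sample_id
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop("sample_id must be non-empty")
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicate sample_id: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (!all(cohort$diagnosis %in% DIAGNOSIS_LEVELS)) {
    stop("diagnosis must be one of ", paste(DIAGNOSIS_LEVELS, collapse = "/"))
  }
  if (!all(cohort$hpv_status %in% HPV_LEVELS)) {
    stop("hpv_status must be one of ", paste(HPV_LEVELS, collapse = "/"))
  }
  for (col in CT_COLUMNS) {
    v <- cohort[[col]]
    bad <- which(!is.na(v) & (v <= 0 | v > 45))
    if (length(bad)) {
      stop(
        "Ct value out of (0,45] in column ", col,
        " for sample ", cohort$sample_id[bad[1]]
      )
    }
  }
  invisible(cohort)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults mirror
#' the published assay protocol: ACTB acceptance at Ct <= 34, spike-in
#' acceptance at Ct < 18.5, k = 20 stratified cross-validation folds, and
#' the two clinical score cut-offs 0.49 (screening) and 0.77 (HSIL
#' confirmation).
#'
#' @param qc list overriding `actb_max_ct` (34), `spikein_max_ct` (18.5),
#'   `min_rna_conc` (100 ng/uL), `min_a260_280` (1.7),
#'   `enforce_wetlab_fields` (FALSE).
#' @param forest list overriding `n_trees` (100), `features_per_split` (3),
#'   `max_depth` (Inf = unlimited), `min_leaf` (1).
#' @param cv list overriding `k` (20) and `stratified` (TRUE).
#' @param interpret list overriding `screen_cutoff` (0.49) and
#'   `confirm_cutoff` (0.77).
#' @param seed integer master seed; every random draw in the pipeline is
#'   derived from it.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(qc = list(), forest = list(), cv = list(),
                      interpret = list(), seed = 1L) {
  cfg <- list(
    qc = utils::modifyList(list(
      actb_max_ct = 34.0, spikein_max_ct = 18.5,
      min_rna_conc = 100.0, min_a260_280 = 1.7,
      enforce_wetlab_fields = FALSE
    ), qc),
    forest = utils::modifyList(list(
      n_trees = 100L, features_per_split = 3L,
      max_depth = Inf, min_leaf = 1L
    ), forest),
    cv = utils::modifyList(list(k = 20L, stratified = TRUE), cv),
    interpret = utils::modifyList(
      list(screen_cutoff = 0.49, confirm_cutoff = 0.77),
      interpret
    ),
    seed = as.integer(seed)
  )
  class(cfg) <- "mc_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config an `mc_config`.
#' @return the config, invisibly; stops on violation.
#' @export
validate_config <- function(config) {
  qc <- config$qc
  fo <- config$forest
  cv <- config$cv
  it <- config$interpret
  stopifnot(
    qc$actb_max_ct > 0, qc$spikein_max_ct > 0,
    fo$n_trees >= 1, fo$min_leaf >= 1, fo$max_depth >= 1,
    cv$k >= 1
  )
  if (fo$features_per_split < 1 || fo$features_per_split > 9) {
    stop("features_per_split must be in 1..9")
  }
  if (!(it$screen_cutoff > 0 && it$screen_cutoff <= it$confirm_cutoff &&
    it$confirm_cutoff < 1)) {
    stop("need 0 < screen_cutoff <= confirm_cutoff < 1")
  }
  invisible(config)
}
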