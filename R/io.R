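# File formats. Canonical interchange is tidy long CSV (sample_id, target,
# ct, plus optional metadata columns); wide CSV (one row per sample) is the
# convenience dialect. Score tables and configs are CSV/JSON.

# Normalise an assay name: lowercase, drop the "hsa-" prefix and all
# punctuation, so "hsa-miR-21-5p", "miR-21" and "mir21" all collapse to the
# same key.
normalize_target <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^hsa-", "", x)
  gsub("[^a-z0-9]", "", x)
}

target_alias_table <- function() {
  c(
    mir21 = "ct_mir21", mir215p = "ct_mir21",
    mir29b = "ct_mir29b", mir29b3p = "ct_mir29b",
    mir145 = "ct_mir145", mir1455p = "ct_mir145",
    mir451 = "ct_mir451a", mir451a = "ct_mir451a", mir451a5p = "ct_mir451a",
    mir1246 = "ct_mir1246", mir12465p = "ct_mir1246",
    mir1290 = "ct_mir1290", mir12903p = "ct_mir1290",
    actb = "ct_actb", ctactb = "ct_actb",
    celmir39 = "ct_celmir39", celmir395p = "ct_celmir39",
    celmir393p = "ct_celmir39", spikein = "ct_celmir39"
  )
}

#' Read a cohort from CSV
#'
#' Two dialects are accepted. `long` (canonical): columns `sample_id`,
#' `target`, `ct`, with optional `diagnosis`, `hpv_status`, `rna_conc`,
#' `a260_280` repeated per row; one row per reaction. Target names are
#' matched case-insensitively against the eight assay names and common
#' aliases ("miR-21", "hsa-miR-21-5p", "ACTB", "cel-miR-39", ...). `wide`:
#' one row per sample with the `ct_*` column names used by [mc_cohort()].
#' Absent or non-numeric Ct values become `NA`; a Ct outside (0, 45] is a
#' hard error naming the offending row.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return an `mc_cohort`; sample order follows first appearance in the
#'   file.
#' @export
read_cohort <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "wide") {
    return(mc_cohort(wide_to_samples(raw), provenance = path))
  }
  need <- c("sample_id", "target", "ct")
  if (!all(need %in% names(raw))) {
    stop("long dialect needs columns: ", paste(need, collapse = ", "))
  }
  aliases <- target_alias_table()
  key <- normalize_target(raw$target)
  unknown <- !key %in% names(aliases)
  if (any(unknown)) {
    stop(
      "unknown target '", raw$target[which(unknown)[1]],
      "'; accepted names (or aliases of): ",
      paste(unname(ASSAY_NAMES), collapse = ", ")
    )
  }
  col <- unname(aliases[key])
  dup <- duplicated(paste(raw$sample_id, col))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(
      "duplicate (sample_id, target) pair: (",
      raw$sample_id[i], ", ", raw$target[i], ")"
    )
  }
  ct <- suppressWarnings(as.numeric(raw$ct))
  bad <- which(!is.na(ct) & (ct <= 0 | ct > 45))
  if (length(bad)) {
    stop("Ct outside (0,45] at data row ", bad[1], " of ", path)
  }
  ids <- unique(raw$sample_id)
  samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (cc in CT_COLUMNS) samples[[cc]] <- NA_real_
  idx <- match(raw$sample_id, ids)
  for (r in seq_len(nrow(raw))) {
    samples[idx[r], col[r]] <- ct[r]
  }
  for (meta in c("diagnosis", "hpv_status", "rna_conc", "a260_280")) {
    if (meta %in% names(raw)) {
      first <- raw[[meta]][match(ids, raw$sample_id)]
      samples[[meta]] <- if (meta %in% WETLAB_COLUMNS) {
        suppressWarnings(as.numeric(first))
      } else {
        ifelse(is.na(first) | !nzchar(first), "UNKNOWN", first)
      }
    }
  }
  mc_cohort(samples, provenance = path)
}

wide_to_samples <- function(raw) {
  if (!"sample_id" %in% names(raw)) stop("wide dialect needs 'sample_id'")
  for (cc in c(CT_COLUMNS, WETLAB_COLUMNS)) {
    if (cc %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[cc]]))
      if (cc %in% CT_COLUMNS) {
        bad <- which(!is.na(v) & (v <= 0 | v > 45))
        if (length(bad)) {
          stop("Ct outside (0,45] at data row ", bad[1], " column ", cc)
        }
      }
      raw[[cc]] <- v
    }
  }
  raw
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]; a complete cohort round-trips exactly
#' (Ct values are written at six decimals).
#'
#' @param cohort an `mc_cohort`.
#' @param path output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  validate_cohort(cohort)
  if (dialect == "wide") {
    out <- as.data.frame(cohort)
    for (cc in c(CT_COLUMNS, WETLAB_COLUMNS)) {
      out[[cc]] <- ifelse(is.na(out[[cc]]), "", sprintf("%.6f", out[[cc]]))
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    present <- CT_COLUMNS[!is.na(unlist(cohort[i, CT_COLUMNS]))]
    if (!length(present)) return(NULL)
    data.frame(
      sample_id = cohort$sample_id[i],
      target = unname(ASSAY_NAMES[present]),
      ct = sprintf("%.6f", unlist(cohort[i, present])),
      diagnosis = cohort$diagnosis[i],
      hpv_status = cohort$hpv_status[i],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-sample scores to CSV
#'
#' Columns: `sample_id`, `mir_cervix` (six decimals, round-trips to 1e-6),
#' `fold`, `category`, `diagnosis`, `hpv_status`.
#'
#' @param results data.frame of scored samples (as from [run_pipeline()] or
#'   [crossval_scores()]); must be non-empty.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results must be a non-empty data.frame")
  }
  cols <- c("sample_id", "mir_cervix", "fold", "category",
            "diagnosis", "hpv_status")
  for (cc in setdiff(cols, names(results))) results[[cc]] <- NA
  out <- results[, cols]
  out$mir_cervix <- sprintf("%.6f", out$mir_cervix)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a score CSV written by [write_scores()]
#'
#' @param path CSV path.
#' @return data.frame with numeric `mir_cervix` and integer `fold`.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$mir_cervix <- as.numeric(df$mir_cervix)
  df$fold <- as.integer(df$fold)
  df
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the [mc_config()] structure; absent fields keep their
#' defaults. `"max_depth": "UNLIMITED"` (or null) maps to unlimited depth.
#'
#' @param path JSON file path.
#' @return an `mc_config`.
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$forest$max_depth) &&
    identical(toupper(as.character(j$forest$max_depth)), "UNLIMITED")) {
    j$forest$max_depth <- Inf
  }
  mc_config(
    qc = as.list(j$qc %||% list()),
    forest = as.list(j$forest %||% list()),
    cv = as.list(j$cv %||% list()),
    interpret = as.list(j$interpret %||% list()),
    seed = j$seed %||% 1L
  )
}

#' Write a pipeline configuration to JSON
#'
#' @param config an `mc_config`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  cfg <- unclass(config)
  if (is.infinite(cfg$forest$max_depth)) cfg$forest$max_depth <- "UNLIMITED"
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
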