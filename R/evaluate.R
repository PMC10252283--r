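# Clinical interpretation and diagnostic-performance evaluation. HSIL is
# the condition-positive class throughout. A score equal to a cut-off is
# called POSITIVE (inclusive boundary, favouring sensitivity at the
# screening cut-off); flip with `inclusive = FALSE`.

#' Binary call at a score cut-off
#'
#' @param score miR-CERVIX values in \[0, 1\].
#' @param cutoff decision threshold.
#' @param inclusive call `POSITIVE` when `score == cutoff` (default TRUE).
#' @return character vector `"POSITIVE"`/`"NEGATIVE"`.
#' @export
classify <- function(score, cutoff, inclusive = TRUE) {
  pos <- if (inclusive) score >= cutoff else score > cutoff
  ifelse(pos, "POSITIVE", "NEGATIVE")
}

#' Three-band clinical category of a score
#'
#' Below the screening cut-off the sample is normal-leaning (green); from
#' the screening to the confirmation cut-off it is elevated (yellow); at or
#' above the confirmation cut-off it is HSIL-confirming (red).
#'
#' @param score miR-CERVIX values.
#' @param screen_cutoff,confirm_cutoff band edges (defaults 0.49 / 0.77).
#' @return factor with levels `NORMAL_LEANING`, `ELEVATED`,
#'   `HSIL_CONFIRMING`.
#' @export
score_category <- function(score, screen_cutoff = 0.49,
                           confirm_cutoff = 0.77) {
  factor(
    ifelse(score >= confirm_cutoff, "HSIL_CONFIRMING",
      ifelse(score >= screen_cutoff, "ELEVATED", "NORMAL_LEANING")
    ),
    levels = c("NORMAL_LEANING", "ELEVATED", "HSIL_CONFIRMING")
  )
}

#' Confusion counts at a cut-off
#'
#' HSIL is condition-positive: a POSITIVE call on an HSIL sample is a true
#' positive, on a NILM sample a false positive.
#'
#' @param scores data.frame with `mir_cervix` and `diagnosis`
#'   (`NILM`/`HSIL`; `UNKNOWN` is an error).
#' @param cutoff decision threshold.
#' @param inclusive see [classify()].
#' @return list of class `mc_confusion`: `tp`, `fp`, `tn`, `fn`, `total`.
#' @export
confusion <- function(scores, cutoff, inclusive = TRUE) {
  if (!all(scores$diagnosis %in% c("NILM", "HSIL"))) {
    stop("confusion counts need NILM/HSIL diagnoses; UNKNOWN present")
  }
  pos <- classify(scores$mir_cervix, cutoff, inclusive) == "POSITIVE"
  hsil <- scores$diagnosis == "HSIL"
  counts <- list(
    tp = sum(pos & hsil), fp = sum(pos & !hsil),
    tn = sum(!pos & !hsil), fn = sum(!pos & hsil)
  )
  counts$total <- counts$tp + counts$fp + counts$tn + counts$fn
  structure(counts, class = "mc_confusion")
}

#' Diagnostic rates from confusion counts
#'
#' All rates are percentages. A rate whose denominator is zero is
#' undefined and reported as `NA`, never 0. Precision is synonymous with
#' PPV. Values carry full precision; round for presentation (the
#' conventional report shows two decimals).
#'
#' @param counts an `mc_confusion` (or list with `tp`, `fp`, `tn`, `fn`).
#' @return list: `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`,
#'   `precision` (percent).
#' @export
metrics <- function(counts) {
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, {
    total <- tp + fp + tn + fn
    ppv <- rate(tp, tp + fp)
    list(
      sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, tn + fp),
      ppv = ppv,
      npv = rate(tn, tn + fn),
      accuracy = rate(tp + tn, total),
      precision = ppv
    )
  })
}

#' ROC curve and AUC
#'
#' The curve is swept over every distinct score (descending) plus a
#' sentinel above the maximum, calling `score >= threshold` positive; AUC
#' is the trapezoidal integral, which equals the probability that a random
#' HSIL sample outscores a random NILM sample with ties counted half.
#'
#' @param score miR-CERVIX values.
#' @param diagnosis matching `NILM`/`HSIL` labels; both must occur.
#' @return list of class `mc_roc`: `roc` (data.frame `threshold`, `tpr`,
#'   `fpr`) and `auc`.
#' @export
roc_auc <- function(score, diagnosis) {
  hsil <- diagnosis == "HSIL"
  if (!any(hsil) || all(hsil)) stop("ROC needs both classes")
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pos <- score >= thresholds[i]
    tpr[i] <- sum(pos & hsil) / sum(hsil)
    fpr[i] <- sum(pos & !hsil) / sum(!hsil)
  }
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(
    list(
      roc = data.frame(threshold = thresholds, tpr = tpr, fpr = fpr),
      auc = auc
    ),
    class = "mc_roc"
  )
}

#' Mann-Whitney U test between two score samples
#'
#' U from rank sums with midranks for ties. The two-sided p-value is exact
#' (by enumeration) when the smaller sample has at most 8 values and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b numeric score samples (non-empty).
#' @return list `U`, `p`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  ht <- stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis rank test across score groups
#'
#' H with tie correction; p from the chi-squared approximation with g - 1
#' degrees of freedom. Group means are reported alongside, as in the
#' conventional three-group (NILM/HPV-, HSIL/HPV-, HSIL/HPV+) display.
#'
#' @param groups named list of at least two non-empty numeric vectors.
#' @return list `H`, `p`, `group_means` (named).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  ht <- stats::kruskal.test(groups)
  list(
    H = unname(ht$statistic), p = ht$p.value,
    group_means = vapply(groups, mean, numeric(1))
  )
}

#' Full diagnostic report for a scored cohort
#'
#' Confusion counts and rates at both clinical cut-offs, the ROC/AUC, the
#' NILM-vs-HSIL Mann-Whitney test, per-group mean scores, and — when HPV
#' status is available — the Kruskal-Wallis test across NILM/HPV(-),
#' HSIL/HPV(-) and HSIL/HPV(+).
#'
#' @param scores data.frame with `mir_cervix`, `diagnosis`, and optionally
#'   `hpv_status`.
#' @param config an [mc_config()] supplying the cut-offs.
#' @return list of class `mc_report`.
#' @export
diagnostic_report <- function(scores, config = mc_config()) {
  it <- config$interpret
  counts_screen <- confusion(scores, it$screen_cutoff)
  counts_confirm <- confusion(scores, it$confirm_cutoff)
  roc <- roc_auc(scores$mir_cervix, scores$diagnosis)
  mw <- mann_whitney(
    scores$mir_cervix[scores$diagnosis == "NILM"],
    scores$mir_cervix[scores$diagnosis == "HSIL"]
  )
  group_means <- tapply(scores$mir_cervix, scores$diagnosis, mean)
  kw <- NULL
  if ("hpv_status" %in% names(scores) &&
    all(scores$hpv_status %in% c("POS", "NEG"))) {
    grp <- list(
      `NILM/HPV-` = scores$mir_cervix[
        scores$diagnosis == "NILM" & scores$hpv_status == "NEG"
      ],
      `HSIL/HPV-` = scores$mir_cervix[
        scores$diagnosis == "HSIL" & scores$hpv_status == "NEG"
      ],
      `HSIL/HPV+` = scores$mir_cervix[
        scores$diagnosis == "HSIL" & scores$hpv_status == "POS"
      ]
    )
    grp <- grp[lengths(grp) >= 1]
    if (length(grp) >= 2) kw <- kruskal_wallis(grp)
  }
  structure(
    list(
      screen = list(
        cutoff = it$screen_cutoff, counts = counts_screen,
        metrics = metrics(counts_screen)
      ),
      confirm = list(
        cutoff = it$confirm_cutoff, counts = counts_confirm,
        metrics = metrics(counts_confirm)
      ),
      roc = roc$roc, auc = roc$auc,
      mann_whitney = mw, kruskal_wallis = kw,
      group_means = as.list(group_means)
    ),
    class = "mc_report"
  )
}

#' Write a diagnostic report to JSON
#'
#' @param report an `mc_report` (ROC curve included) or the `report`
#'   element of [run_pipeline()] output.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(
    strip(report), path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
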