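# Base-graphics displays of a scored cohort: ranked score bars with a
# diagnosis colour strip, and the ROC curve.

#' Ranked score bars with diagnosis strip
#'
#' Black bars show each sample's miR-CERVIX value in ascending order; the
#' strip underneath colours the morphological diagnosis (green NILM, red
#' HSIL). Dashed lines mark the two clinical cut-offs.
#'
#' @param scores data.frame with `mir_cervix` and `diagnosis`.
#' @param screen_cutoff,confirm_cutoff cut-offs to mark.
#' @return invisibly, the plotting order.
#' @export
plot_scores <- function(scores, screen_cutoff = 0.49, confirm_cutoff = 0.77) {
  ord <- order(scores$mir_cervix)
  s <- scores[ord, ]
  graphics::barplot(s$mir_cervix,
    col = "black", border = NA, space = 0,
    ylim = c(-0.08, 1), ylab = "miR-CERVIX", xlab = "samples (ranked)"
  )
  graphics::rect(
    seq_len(nrow(s)) - 1, -0.08, seq_len(nrow(s)), -0.02,
    col = ifelse(s$diagnosis == "HSIL", "red3", "green4"), border = NA
  )
  graphics::abline(h = c(screen_cutoff, confirm_cutoff), lty = 2,
                   col = "grey40")
  invisible(ord)
}

#' ROC curve plot
#'
#' @param report an `mc_report` (from [diagnostic_report()] or
#'   `run_pipeline()$report`).
#' @return invisibly, the AUC.
#' @export
plot_roc <- function(report) {
  roc <- report$roc
  graphics::plot(roc$fpr, roc$tpr,
    type = "l", lwd = 2,
    xlab = "1 - specificity", ylab = "sensitivity",
    main = sprintf("AUC = %.3f", report$auc)
  )
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(report$auc)
}
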