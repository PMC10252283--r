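# Synthetic Ct-level cohort generator. Emulates the two-group study
# structure the analysis assumes: NILM vs HSIL with an HPV(+)/HPV(-)
# substructure inside HSIL, a shared per-sample Ct offset (input-quantity
# variation that the reciprocal pairs are designed to cancel), independent
# per-reaction noise, and control-reaction QC failures at a fixed rate.

#' Default simulation parameters
#'
#' Cohort shape follows the study design the pipeline targets: 114 NILM and
#' 112 HSIL enrolled, ~17% control-reaction failure rate (38/226), HPV
#' positivity 72/101 within HSIL and 1/87 within NILM, and attenuated
#' (scale 0.6) marker effects in HSIL/HPV(-) samples so that group sits
#' between NILM and HSIL/HPV(+). Baseline Ct values are plausible qPCR
#' magnitudes (markers 23-29 cycles, ACTB 28, spike-in 15.5 — leaving
#' three cycles of headroom under the 18.5 acceptance bound, so control
#' reactions of intact samples essentially never fail by chance and the
#' realised QC attrition tracks `qc_fail_rate`). Effect sizes
#' (in cycles; negative = up-regulated, i.e. earlier amplification) and the
#' two noise components are calibration choices producing clear but
#' imperfect class separation — overlapping score distributions rather than
#' a separable toy.
#'
#' @return list of class `mc_sim_params`.
#' @export
default_sim_params <- function() {
  p <- list(
    n_nilm = 114L,
    n_hsil = 112L,
    baseline_ct = c(
      ct_mir21 = 25, ct_mir29b = 26, ct_mir145 = 27,
      ct_mir451a = 23, ct_mir1246 = 28, ct_mir1290 = 29
    ),
    effect_hsil = c(
      ct_mir21 = 0, ct_mir29b = 0.9, ct_mir145 = -1.1,
      ct_mir451a = 1.1, ct_mir1246 = -1.3, ct_mir1290 = -0.9
    ),
    hpv_frac_hsil = 72 / 101,
    hpv_frac_nilm = 1 / 87,
    effect_hpvneg_scale = 0.6,
    sample_offset_sd = 1.5,
    reaction_noise_sd = 1.1,
    qc_fail_rate = 38 / 226,
    actb_mean = 28,
    spikein_mean = 15.5,
    seed = 1L
  )
  class(p) <- "mc_sim_params"
  validate_sim_params(p)
  p
}

#' Validate simulation parameters
#'
#' @param params an `mc_sim_params` list.
#' @return the params, invisibly; stops on violation.
#' @export
validate_sim_params <- function(params) {
  marker_cols <- setdiff(CT_COLUMNS, CT_CONTROLS)
  stopifnot(
    params$n_nilm >= 1, params$n_hsil >= 1,
    all(marker_cols %in% names(params$baseline_ct)),
    all(marker_cols %in% names(params$effect_hsil)),
    params$hpv_frac_hsil >= 0, params$hpv_frac_hsil <= 1,
    params$hpv_frac_nilm >= 0, params$hpv_frac_nilm <= 1,
    params$effect_hpvneg_scale >= 0, params$effect_hpvneg_scale <= 1,
    params$sample_offset_sd >= 0, params$reaction_noise_sd >= 0,
    params$qc_fail_rate >= 0, params$qc_fail_rate <= 1
  )
  invisible(params)
}

#' Simulate a Ct-level cohort
#'
#' Each sample's Ct for marker m is
#' `baseline_ct[m] + group_effect(m) + sample_offset + reaction_noise`,
#' where the group effect is 0 for NILM, `effect_hsil[m]` for HSIL/HPV(+)
#' and `effect_hsil[m] * effect_hpvneg_scale` for HSIL/HPV(-). The sample
#' offset (shared by all eight reactions of a sample) models input-quantity
#' variation; reaction noise is independent per reaction. ACTB inherits the
#' sample offset (it tracks input material); the spike-in does not (it is
#' added at fixed quantity). With probability `qc_fail_rate` a sample's
#' control reactions are spoiled — ACTB pushed above 34 or the spike-in to
#' 18.5 or above, chosen by a fair coin — so the QC gate excludes it.
#'
#' @param params an `mc_sim_params` list, e.g. [default_sim_params()].
#' @return an `mc_cohort` with diagnosis and HPV labels attached;
#'   deterministic given `params$seed`.
#' @export
simulate_cohort <- function(params = default_sim_params()) {
  validate_sim_params(params)
  marker_cols <- setdiff(CT_COLUMNS, CT_CONTROLS)
  n <- params$n_nilm + params$n_hsil
  with_seed(params$seed, {
    diagnosis <- c(rep("NILM", params$n_nilm), rep("HSIL", params$n_hsil))
    hpv_prob <- ifelse(diagnosis == "HSIL",
      params$hpv_frac_hsil, params$hpv_frac_nilm
    )
    hpv <- ifelse(rbinom(n, 1, hpv_prob) == 1, "POS", "NEG")
    effect_scale <- ifelse(diagnosis == "NILM", 0,
      ifelse(hpv == "POS", 1, params$effect_hpvneg_scale)
    )
    offset <- rnorm(n, 0, params$sample_offset_sd)
    df <- data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      diagnosis = diagnosis, hpv_status = hpv,
      stringsAsFactors = FALSE
    )
    for (m in marker_cols) {
      df[[m]] <- params$baseline_ct[[m]] +
        effect_scale * params$effect_hsil[[m]] +
        offset + rnorm(n, 0, params$reaction_noise_sd)
    }
    df$ct_actb <- params$actb_mean + offset +
      rnorm(n, 0, params$reaction_noise_sd)
    df$ct_celmir39 <- params$spikein_mean +
      rnorm(n, 0, params$reaction_noise_sd)
    # injected control-reaction failures, split evenly between the two
    # control assays
    fail <- rbinom(n, 1, params$qc_fail_rate) == 1
    via_actb <- rbinom(n, 1, 0.5) == 1
    spoil_actb <- fail & via_actb
    spoil_spike <- fail & !via_actb
    df$ct_actb[spoil_actb] <- 34 + runif(sum(spoil_actb), 0.5, 4)
    df$ct_celmir39[spoil_spike] <- 18.5 + runif(sum(spoil_spike), 0, 2.5)
    mc_cohort(df, provenance = sprintf("synthetic (seed=%d)", params$seed))
  })
}
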