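# Reciprocal-pair predictors. Each QC-passing sample's six marker Ct
# values collapse to nine ratios chi_1..chi_9 = 2^(Ct_marker - Ct_ref),
# pairing every up-regulated marker (miR-145, miR-1246, miR-1290; outer,
# marker-major order) with every stable/down-regulated reference (miR-21,
# miR-29b, miR-451a; inner). Because both members share the sample's input
# quantity, a constant shift of all Ct values cancels exactly — the ratios
# are reference-free.

#' Amplification ratio of a reciprocally regulated pair
#'
#' `2^(ct_x - ct_y)`: one cycle of difference is one doubling. Values below
#' 1 mean the first assay amplified earlier (more abundant) than the
#' second.
#'
#' @param ct_x,ct_y Ct values (cycles); must be present and finite.
#' @return positive real; vectorised.
#' @export
pair_ratio <- function(ct_x, ct_y) {
  if (anyNA(ct_x) || anyNA(ct_y)) {
    stop("pair_ratio requires both Ct values; got MISSING")
  }
  2^(ct_x - ct_y)
}

#' Labels of the nine predictor pairs
#'
#' @return data.frame with columns `chi` (`chi1`..`chi9`), `marker`,
#'   `reference` in the fixed marker-major ordering.
#' @export
chi_pair_labels <- function() {
  grid <- expand.grid(
    reference = CT_REFS, marker = CT_MARKERS,
    stringsAsFactors = FALSE
  )[, c("marker", "reference")]
  data.frame(
    chi = paste0("chi", 1:9),
    marker = unname(ASSAY_NAMES[grid$marker]),
    reference = unname(ASSAY_NAMES[grid$reference]),
    stringsAsFactors = FALSE
  )
}

#' Predictor vector for one sample
#'
#' @param sample one-row data.frame (or list) carrying the six marker
#'   `ct_*` fields; all must be present.
#' @return named numeric 9-vector `chi1`..`chi9`.
#' @export
predictor_vector <- function(sample) {
  for (m in c(CT_MARKERS, CT_REFS)) {
    if (is.null(sample[[m]]) || is.na(sample[[m]])) {
      stop("missing Ct for ", ASSAY_NAMES[[m]])
    }
  }
  chi <- numeric(9)
  i <- 0L
  for (m in CT_MARKERS) {
    for (r in CT_REFS) {
      i <- i + 1L
      chi[i] <- pair_ratio(sample[[m]], sample[[r]])
    }
  }
  names(chi) <- paste0("chi", 1:9)
  chi
}

#' Predictor matrix for a cohort
#'
#' @param cohort an `mc_cohort` whose samples all have complete marker Ct
#'   values (i.e. QC-passing).
#' @return n x 9 numeric matrix, rownames = sample ids, colnames
#'   `chi1`..`chi9`.
#' @export
predictor_matrix <- function(cohort) {
  validate_cohort(cohort)
  X <- matrix(NA_real_, nrow(cohort), 9,
    dimnames = list(cohort$sample_id, paste0("chi", 1:9))
  )
  for (i in seq_len(nrow(cohort))) {
    X[i, ] <- predictor_vector(cohort[i, ])
  }
  X
}
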