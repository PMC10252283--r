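---
title: "miR-CERVIX scoring: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miR-CERVIX scoring: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircervix)
```

## The problem

The panel quantifies six marker miRNAs in exfoliated cervical epithelium
by RT-qPCR, alongside two control reactions: amplification of a conserved
non-translated ACTB region (material quantity/quality) and a cel-miR-39
spike-in added at fixed concentration before processing (enzymatic
efficiency). The goal is a single per-sample score — the miR-CERVIX value
in [0, 1] — separating normal cytology (NILM) from high-grade squamous
intraepithelial lesions (HSIL), with two clinically motivated cut-offs:
a screening threshold and a high-specificity HSIL-confirmation threshold.

## Pipeline stages

### 1. Control-reaction QC

A sample is analyzable iff

* ACTB Ct is present and **≤ 34** (exclusion is *strictly above* 34, so a
  Ct of exactly 34.0 passes);
* spike-in Ct is present and **strictly under 18.5** (so 18.5 itself
  fails) — the two bounds deliberately have opposite inclusivity,
  matching how each acceptance rule is phrased in the assay protocol;
* all six marker Ct values are present.

Missing marker values exclude the sample (reason `MISSING_MARKER`) rather
than being imputed: the predictor stage needs all six values, and a
cap-at-max-cycle imputation would bias the ratios silently in one
direction. Wet-lab pre-assay gates (RNA ≥ 100 ng/µL, A260/280 ≥ 1.7) are
recorded but only enforced when `enforce_wetlab_fields` is on, since they
apply upstream of the assay and synthetic data need not model
spectrophotometry. QC classifies, it never hard-fails; every excluded
sample carries all applicable machine-readable reason codes so cohort
attrition is auditable.

### 2. Reciprocal-pair predictors

Each up-regulated marker (miR-145-5p, miR-1246-5p, miR-1290-3p) is paired
with each stable/down-regulated reference (miR-21-5p, miR-29b-3p,
miR-451a-5p):

$$\chi_i = 2^{\,Ct_\text{marker} - Ct_\text{reference}}, \qquad i = 1,\dots,9.$$

The indexing is marker-major (χ1 = miR-145/miR-21, χ2 = miR-145/miR-29b,
…, χ9 = miR-1290/miR-451a) and fixed, so importance vectors are
comparable across runs. The orientation (marker Ct in the exponent's
first position) is a convention; since lower Ct means higher abundance,
up-regulation of a marker *lowers* its χ values. The classifier is
orientation-agnostic — only consistency matters, and it is documented
here. The base-2 exponent assumes perfect amplification efficiency;
efficiency-corrected quantification is out of scope.

The construction is reference-free: both members of a pair share the
sample's input quantity, so a constant shift of all Ct values of a sample
cancels exactly (`predictor_vector(sample + c) == predictor_vector(sample)`,
tested as an exact identity, not to a tolerance).

### 3. Bagged tree ensemble and cross-validated scoring

The classifier is an ensemble of CART-style binary trees:

* each tree trains on a bootstrap resample (size n, with replacement);
* at each node `features_per_split` predictor indices are drawn without
  replacement and the axis-aligned split minimising Gini impurity is
  taken; ties are broken toward the first candidate encountered in draw
  order, which is deterministic given the seed;
* growing stops at pure nodes, nodes below `2 × min_leaf` samples, or
  `max_depth`; leaves store class frequencies;
* a sample's score is the mean leaf HSIL-probability over trees (soft
  voting — "averaging the results" is read as probability averaging, not
  hard majority vote);
* per-predictor importances are the normalised total Gini impurity
  decrease across all trees (if no split is ever made the importance
  vector falls back to uniform).

Under stratified k-fold cross-validation each sample is scored exactly
once, by the model trained without its fold (*out-of-fold* scoring). This
reading — one score per sample, rather than averaging k models over the
training data — is what a per-sample ranked-score display requires. The
alternative, averaging all k fold models, is retained as
`score_external()` for samples outside the training cohort. Fold
assignment deals samples round-robin along a randomised class-blocked
order, so overall fold sizes differ by at most one *and* per-class counts
differ by at most one; stratification is on by default because at k = 20
with ~90 samples per class, unstratified folds can strand a training
split without one class.

Defaults — 100 trees, 3 features per split (⌊√9⌋), unlimited depth,
min_leaf 1, Gini — are conventional random-forest choices; the tree
count and subset size are configurable and nothing downstream depends on
their exact values. Tree growing is implemented in C++ with a
self-contained splitmix64 RNG seeded per tree, so a single integer seed
reproduces every bootstrap and feature draw bit-for-bit across platforms,
independent of R's global RNG state.

### 4. Interpretation and evaluation

A score at or above the cut-off is POSITIVE (inclusive boundary,
favouring sensitivity at the screening cut-off; flippable via
`inclusive = FALSE`). The three-band category (`NORMAL_LEANING` below
0.49, `ELEVATED` in [0.49, 0.77), `HSIL_CONFIRMING` at ≥ 0.77) mirrors
the intended green–yellow–red clinical colour scale; the band edges come
from configuration. The published cut-offs are treated as external
configuration — the package does not re-derive them (no Youden
optimisation), because whether they were chosen on the same data used
for cross-validation is not documented.

Diagnostic rates are percentages computed from confusion counts with
HSIL as condition-positive; a rate whose denominator is zero is
**undefined (`NA`), never 0**. Precision is reported as a synonym of PPV.
Values carry full precision internally; two decimals is presentation.

The ROC is swept over all distinct scores plus a sentinel, and the AUC is
the trapezoidal integral — algebraically equal to the probability that a
random HSIL sample outscores a random NILM one with ties counted half,
which the test suite verifies against an O(n²) pair-counting oracle and
against pROC. The Mann–Whitney U test uses exact enumeration when the
smaller group has ≤ 8 values and no ties, otherwise the normal
approximation with tie and continuity correction; the Kruskal–Wallis H
uses the tie-corrected statistic with the χ² approximation and reports
per-group mean scores alongside (the NILM/HPV−, HSIL/HPV−, HSIL/HPV+
display). Both go through the corresponding `stats` routines.

## The synthetic cohort generator

No patient-level data are distributed with the assay's publications, so
the generator is the package's study stand-in, with defaults fixed to the
documented cohort shape: 114 NILM and 112 HSIL enrolled, a 38/226 (~17%)
control-reaction failure rate, HPV positivity 72/101 within HSIL and 1/87
within NILM.

The Ct model is the minimal two-level structure under which
reciprocal-pair normalization is meaningful:

$$Ct_{s,m} = \text{baseline}_m + \text{effect}_m(\text{group}_s) + u_s + \varepsilon_{s,m}$$

with a per-sample offset $u_s \sim N(0, 1.5^2)$ shared by all eight
reactions (input-quantity variation — exactly what the χ ratios cancel)
and independent per-reaction noise $\varepsilon \sim N(0, 1.1^2)$. Group
effects are 0 for NILM, the full per-miRNA effect for HSIL/HPV(+), and
attenuated by a factor 0.6 for HSIL/HPV(−) — the attenuation produces the
intermediate score level observed for that group; its exact biology is
unknown, so the scale is a free parameter. Effect sizes (up-regulated
markers −0.9 to −1.3 cycles, references +0.9 to +1.1, miR-21 exactly 0 as
the stable normalizer) are calibration choices, not published facts — no
per-miRNA fold changes between NILM and HSIL are reported anywhere — and
were chosen once to give clear but imperfect separation: overlapping
score distributions, a cross-validated AUC well inside (0.5, 1), and
misclassified samples on both sides, as in the published ranked-score
display.

ACTB inherits the sample offset (it tracks input material, baseline 28
cycles); the spike-in does not (fixed quantity per reaction). The
spike-in baseline is 15.5 cycles — about three cycles of headroom under
the 18.5 acceptance bound — so control reactions of intact samples
essentially never fail by chance (< 1 sample per cohort in expectation)
and realised attrition tracks the injected `qc_fail_rate`. With a
baseline too close to the bound, reaction noise alone would inflate
attrition far beyond the intended rate. Injected failures spoil exactly
one control, chosen by a fair coin, since which control drove the
documented exclusions is not reported.

What the generator does **not** model: amplification-efficiency
differences between assays, plate/position effects, RT chemistry,
heteroscedastic noise at high Ct, label noise in the cytological
diagnosis, and any correlation structure among the six markers beyond
the shared offset. Passing tests therefore demonstrate that the pipeline
recovers structure *of this form*; they are not evidence about assay
performance on clinical material.

## Numerical and testing choices

* All randomness flows from one integer master seed through derived
  sub-seeds (R's RNG for cohort simulation and fold assignment; the C++
  splitmix64 stream for tree growing), giving byte-identical outputs
  across repeated runs.
* Split search requires a strictly positive Gini gain (> 1e-12); a node
  with no informative candidate feature becomes a leaf.
* Score files print six decimals; round-trips are guaranteed to 1e-6.
* Monte-Carlo test sizes are chosen for tight-but-fast checks: 100 seeds
  for the QC-attrition expectation, 20 seeds each for the
  label-permutation null (cohorts of 60, k = 5, 50 trees) and the
  importance-recovery check (60 samples, 50 trees), 10⁵ shuffles for the
  Mann–Whitney permutation comparison. Full-scale runs (226 samples,
  k = 20, 100 trees) take well under two seconds.

## Known limitations

* The ensemble's probability estimates are uncalibrated beyond averaging;
  scores are ranks-with-meaning, not posterior probabilities.
* Two-class design: intermediate cytology (LSIL, ASC-US, ASC-H) is out of
  scope, as are instrument-native export formats (the canonical input is
  tidy long CSV) and re-derivation of the clinical cut-offs.
* An external binary test (e.g. an HPV screen) can be evaluated through
  the same confusion/metrics path, but without an underlying continuous
  score no ROC can be produced for it.
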