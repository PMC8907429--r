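---
title: "Methods: rank-based gene-pair signatures for immunotherapy response"
author: "irgpi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based gene-pair signatures for immunotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

A gene pair `A|B` scores 1 in a sample when A's expression strictly exceeds
B's, and 0 otherwise — including exact ties. The index of a sample is the
weighted sum of its pair scores with multivariate Cox coefficients,
`IRGPI(s) = Σ_i score_i(s) · β_i`; higher values mean higher hazard and
lower probability of response (CR/PR). Because the score consumes only the
within-sample ordering of two genes, the whole construction is exactly
invariant to any strictly increasing per-sample transformation of the
expression values. This is the method's central claim and the reason
cohorts measured on different platforms can be concatenated ("meta cohort")
with no normalisation; the package asserts the invariance as an exact
(`identical()`) property test, not an approximate one.

Assumptions worth keeping in mind:

- proportional hazards for the survival screening and the Cox fit;
- the binary pair score discards magnitude entirely — two samples where
  A beats B by 0.1% and by 100-fold are indistinguishable;
- ties score 0, which orients every tie against the pair. Ties have
  probability zero for continuous expression but can occur in
  zero-inflated data, where `A|B` and `B|A` are then *both* 0 and the
  complementarity `score(A|B) + score(B|A) = 1` fails. The complementarity
  property is therefore claimed (and tested) only for tie-free data.

# The discovery chain

1. **Gene universe.** Sorted intersection of gene symbols across all
   cohorts, optionally pre-intersected with a user-supplied immune-gene
   list (ImmPort-style). No gene catalogue is packaged: curated lists are
   versioned resources the user should pin themselves. Symbols are matched
   case-sensitively after whitespace trimming, with no alias resolution;
   duplicate expression rows keep the highest-mean row.
2. **Pairs.** By default one pair per unordered gene couple with the
   lexicographically smaller symbol first (`n(n−1)/2` pairs). The reversed
   pair is the exact complement of the forward one — identical survival
   split, flipped coefficient sign — so enumerating both ("both" mode,
   available for fidelity experiments) only duplicates information.
3. **Constant-pair filter.** A pair whose score is 0 or is 1 in strictly
   more than 80% of *any* cohort's samples is removed: it cannot separate
   that cohort. "Over 80%" is a strict inequality — exactly 80% is kept.
   The filter streams over row blocks, and a test asserts the result is
   independent of the block size.
4. **Screening.** One two-group log-rank test per pair against overall
   survival (PFS is available as an option), Benjamini–Hochberg FDR across
   pairs, candidates at FDR strictly below 0.001. Pairs that are constant
   in the analysed subset get p = 1 with a flag rather than an error, so
   the result stays aligned with the pair list. A univariate Cox Wald mode
   is provided; for a binary covariate it is asymptotically equivalent to
   the log-rank test, and a test requires agreement within |Δp| ≤ 0.02 at
   n ≥ 100.
5. **Signature fit.** Two stages: an L1-penalised Cox partial-likelihood
   fit over all candidates, with the penalty chosen by 10-fold
   cross-validated partial-likelihood deviance (fold assignment is drawn
   from a mandatory seed, so fitted signatures are reproducible), then an
   unpenalised multivariate Cox refit on the pairs with non-zero penalised
   coefficients. The two-stage design is the standard answer to having far
   more candidates than events (hundreds of candidates against ~100
   events); when candidates number at most one fifth of the events the
   penalised stage is skipped. Pairs showing separation (monotone
   likelihood) are dropped with a warning and the model refit; an empty
   penalised selection raises a typed error rather than a crash. No
   stepwise selection and no elastic-net grid are offered.

# Evaluation

- **ROC / Youden.** Thresholds are midpoints between consecutive distinct
  scores plus ±∞ sentinels; under the default direction a low score
  predicts response, and a sample is called positive when its score is at
  or below the threshold. The trapezoidal AUC equals the tie-corrected
  Mann–Whitney probability (asserted to 1e-12). The Youden cutoff
  maximises J = sensitivity + specificity − 1, with ties broken toward
  higher sensitivity and then the lower threshold — an arbitrary but
  deterministic rule.
- **Group comparison.** Log-rank p from the same implementation used in
  screening (asserted identical), Kaplan–Meier curves via the product-limit
  estimator, and a binary-covariate Cox hazard ratio with a Wald 95% CI
  using Breslow tie handling. Median survival is reported as undefined
  (NA) when a curve never reaches 0.5.
- **Survival-driven cutpoint.** For cohorts without response labels, an
  exhaustive scan over the distinct score values keeps splits where both
  groups hold at least 10% of samples and returns the cutoff minimising
  the log-rank p. This is a minimal X-tile-style scan: no
  training/validation split and no minimum-p correction, so the reported
  p-value is optimism-biased — a message says so every time, and the full
  scan table is returned so users can apply their own correction.
- **Meta-analysis.** Fixed-effect inverse-variance pooling of per-cohort
  log hazard ratios with Cochran's Q, I² = max(0, (Q − df)/Q)·100 and a
  chi-square heterogeneity p. Fixed effect (not random) matches the
  homogeneous-cohorts setting the pooling is meant for; with two or three
  studies a between-study variance estimate would be noise anyway.

# The bundled signature

`load_bundled_signature()` returns a published 31-pair melanoma
ICI-response signature with multivariate Cox coefficients at full printed
precision, checksum-verified at load. Genes recur across pairs exactly as
published (IDO1 and IRF1 each open two pairs; IL1R1 closes three); no
deduplication is applied, and the distinct-gene count is computed from the
parsed table rather than asserted. Scores are bounded by the sums of the
negative and positive coefficients, a property every scored sample is
tested against.

# The synthetic generator

`generate_cohorts()` emulates a multi-cohort ICI discovery setting.
Defaults: three cohorts of 41/28/51 samples (the shape of a three-study
pooled discovery set), responder fraction 53/120, exponential survival
with baseline hazard log(2)/25 per month (median survival 25 months at
index 0), 30% censoring, and per-cohort strictly increasing platform
transforms (identity, square, log1p, affine). Times are in months;
event = 1 means the event occurred.

The signal is planted at the *ordering* level: each sample draws a latent
prognosis class, and for every planted pair the two genes' values are
swapped within the sample, when needed, so the indicator takes the
class-favoured orientation except with probability `pair_flip_probability`
(default 0.10; the stated strong-signal recovery conditions use 0.05).
Planting orderings rather than mean shifts makes the indicator
distribution exactly controlled regardless of the marginal expression
model — which is the property that makes recovery targets analytic — and
requires planted pairs to use disjoint genes. The latent index
`L = Σ β_i · indicator_i` then drives an exponential proportional-hazards
survival time (hazard `h0 · exp(beta_surv · L)`, censored by an
independent exponential calibrated by root-finding so the expected
censored fraction matches `censoring_rate`) and a logistic response model
centred at the cohort median index. All randomness flows from one root
seed through named per-cohort, per-phase substreams, so the full
simulate → build → score → evaluate chain is bit-reproducible (asserted by
checksum in the tests).

What the generator does *not* emulate: negative-binomial RNA-seq count
noise, batch effects beyond monotone transforms, gene–gene correlation
structure, informative censoring, or melanoma biology. Passing tests
demonstrate the pipeline's statistical machinery is correct and calibrated
under the generative model — not that any fitted signature will transfer
to real tumours.

# Numerical and calibration choices

- Strict inequalities throughout: pair score needs strictly greater
  expression, candidate selection needs FDR strictly below threshold,
  constancy means strictly more than the threshold fraction.
- The null calibration of the screening test is asserted at n = 200 per
  replicate over 2000 replicates. The log-rank reference distribution is
  asymptotic; at n = 40 the test itself (ours matches
  `survival::survdiff` to 1e-8) is mildly anti-conservative, with a
  measured type-I error near 0.059, converging toward the nominal 0.05 by
  n = 200. The calibration claim is about the asymptotic regime and is
  tested there.
- Coefficient-sign recovery is asserted at n = 500 over 100 seeded
  replicates. The ten planted indicators are strongly collinear — one
  latent class drives them all — so individual multivariate Cox
  coefficients stabilise much more slowly than marginal screening recall
  (which is asserted at n = 300); at n = 300 the all-signs-correct rate is
  measurably below the n = 500 rate.
- Test and acceptance problem sizes (gene universes of 20–100, cohorts of
  tens to hundreds of samples, 2000 null replicates, 100 recovery
  replicates) are chosen so the whole suite runs in well under a minute of
  compute per file while leaving the asserted properties sharp; the
  method's statistics do not depend on scale beyond the calibration notes
  above.

# Known limitations

- The minimum-p cutpoint scan inherits the optimism of every minimum-p
  procedure; its p-value should not be reported as a confirmatory result.
- The lasso-then-refit coefficients are post-selection estimates; their
  nominal standard errors do not account for the selection step.
- Binary pair scores waste information when expression differences are
  informative in magnitude; this is the price of exact platform
  invariance.
- ssGSEA here implements the Barbie-style running sum with rank-value
  weights (`alpha = 0.25`, normalisation off by default) and is intended
  for scoring user-supplied signatures; deconvolution methods (ESTIMATE,
  CIBERSORT) are deliberately out of scope — their per-sample outputs can
  be fed into `compare_feature_by_group()` as ordinary features. The demo
  GMT shipped under `extdata` is synthetic and carries no biological
  meaning.
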