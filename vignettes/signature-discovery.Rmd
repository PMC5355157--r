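---
title: "Discovering and validating a prognostic gene signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and validating a prognostic gene signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

## The analysis this package implements

Tumor transcriptomes carry prognostic information: some genes' expression
levels track how quickly a patient's disease will recur. `progsig`
implements the classic discovery arc for turning several public
case-control expression studies plus a survival cohort into a compact,
weighted prognostic signature:

1. **Cross-study differential-expression consensus.** Each tumor-vs-normal
   study is tested per feature (Welch *t* on log2 values, BH adjustment);
   a feature survives only if *every* study calls it in the same direction
   at a fold-change cutoff of 1.5 and adjusted p < 0.01. Direction
   consistency across independent cohorts is the robustness filter — a
   feature up in three studies and down in one is discarded.
2. **Per-gene survival screen.** For each surviving gene the cohort is
   split at the median expression; groups are compared by the log-rank
   test and the hazard ratio comes from a univariate Cox fit on the
   high-vs-low indicator. Significance is Bonferroni-controlled at
   `alpha / m`, with `m` the number of genes actually screened (for a
   795-feature panel at alpha = 0.05 the bound is 6.3e-05).
3. **Co-expression architecture.** A signed graph over the screened genes:
   edges where the Spearman correlation satisfies |rho| >= 0.6 and the
   Bonferroni-adjusted p-value over all unordered pairs passes 0.05.
   Positive-edge communities describe functional cliques; *negative
   bridges* — outside genes with several negative edges into a community —
   flag candidate suppressors of that community's program.
4. **Stability selection.** Repeated train/test resamples (by default 60
   draws of 300 patients from a 393-patient cohort, leaving 93 for
   testing); SPSS-style forward-conditional Cox selection over the
   candidate genes on every training set; genes selected in **more than
   half** of the resamples form the signature.
5. **Weighted score and validation.** Per-split forced-entry Cox refits
   give coefficient vectors whose average `beta_mean` weights the score
   `score_i = sum_g beta_mean_g * x_gi`. Test sets are dichotomized at the
   averaged training-median cutpoint and summarized as a forest of
   hazard-ratio intervals; external cohorts are dichotomized at their own
   median score, optionally after refitting betas on that cohort; a
   multivariate forced-entry Cox checks independence from clinical
   covariates, and subtype-stratified log-rank tests probe
   subtype-specific behavior.

All survival statistics come from the package's own kernel:
`km_estimate()`, `logrank_test()`, `cox_fit()` (Newton–Raphson on the
Efron- or Breslow-corrected partial likelihood) and
`cox_forward_conditional()`. The test suite cross-checks the kernel
against the independent `survival` package and against brute-force
maximization of the partial likelihood written from its definition.

## A small end-to-end run

```{r pipeline, eval = FALSE}
# four case-control studies sharing one planted DE truth
sim <- simulate_case_control(n_features = 2000, n_tumor = 40, n_normal = 40,
                             de_fraction = 0.1, effect_lfc = 1.5,
                             noise_sd = 0.3, seed = 11)
studies <- simulate_multistudy(4, sim$truth,
                               list(c(40, 7), c(42, 143), c(5, 5), c(72, 36)),
                               study_shift_sd = 0.5, seed = 12)
cons <- consensus(lapply(studies, differential_expression))

# a survival cohort with a planted 12-gene signature
mat <- simulate_case_control(100, 200, 193, de_fraction = 0,
                             effect_lfc = 1, noise_sd = 1, seed = 7)$matrix
set.seed(8)
genes <- sample(mat$feature_ids, 12)
coh <- simulate_survival(mat, genes, rep(c(0.5, -0.5), 6),
                         censor_rate = 0.3, seed = 9)

plan  <- make_splits(393, 300, k = 60, seed = 10)
sel   <- select_signature(mat, coh, candidates = mat$feature_ids, plan)
model <- fit_signature_betas(mat, coh, sel, plan)
forest <- evaluate_test_sets(mat, coh, model, plan)
```

## What the generators emulate — and what they do not

The synthetic-data module exists so that every stage is testable against
known ground truth without downloading the original microarray and
RNA-seq cohorts. Its defaults encode the study design the pipeline is
meant for:

* **Case-control studies** (`simulate_case_control`): log2-scale
  expression, per-feature baselines uniform on 4–12 (the usual microarray
  intensity range), Gaussian within-class noise (`noise_sd = 0.3`,
  a typical post-normalization residual spread), a planted DE fraction
  whose signed log2 effects have magnitude at least `effect_lfc`
  (default 1.5, i.e. comfortably above the pipeline's fold-1.5 call
  threshold of 0.585 log2 units). The planted count is
  `floor(n_features * de_fraction)` with one seeded Bernoulli draw for the
  remainder. The four default study sizes used in the tests (40/7,
  42/143, 5/5, 72/36 tumor/normal) mirror a realistic mix of small and
  large cohorts totalling about 160 carcinomas and 190 normals.
* **Batch effects** (`simulate_multistudy`): an additive per-feature
  Gaussian shift per study (`study_shift_sd = 0.5`) — the simplest model
  that makes cross-study consensus non-trivial while preserving effect
  directions.
* **Correlated blocks** (`simulate_correlated_blocks`): a one-factor
  Gaussian model per block; members load with `sqrt(within_rho)`, giving
  exactly the target pairwise correlation. A negative hub loads on the
  opposed block's factor with weight `hub_rho / sqrt(within_rho)`, which
  bounds attainable hub correlations at `|hub_rho| <= sqrt(within_rho)`
  (requests outside the bound are an error, not silently truncated).
  A side effect worth knowing: hubs opposing the same block are mutually
  *positively* correlated (`hub_rho^2 / within_rho`), so with strong
  settings they can form a small positive community of their own —
  exactly as a coherent suppressor module would in real data.
* **Survival** (`simulate_survival`): a Weibull proportional-hazards
  model (default shape 1.5, scale 5 — event times loosely resembling
  relapse on a scale of years) with the linear predictor centered, and
  independent exponential censoring whose rate is solved numerically so
  the expected censored fraction matches `censor_rate` (default 0.3).

Not emulated: library-size and probe-saturation artifacts, platform
differences, copy-number or mutation structure, informative censoring,
or non-proportional hazards. Passing tests therefore demonstrate that the
pipeline's statistics behave as designed under a clean proportional-
hazards, Gaussian-noise world — not that any particular clinical dataset
satisfies those assumptions. The original cohorts' source data are never
downloaded; where a reference object is unobtainable the tests construct
a synthetic stand-in and say so.

## Numerical and procedural choices

* **Expression scale.** All matrices are treated as log2-scale; fold
  change between classes is `2^(mean difference)`. The fold cutoff is
  applied as `2^|log2fc| >= 1.5`, equivalent to `|log2fc| >= log2(1.5)`.
* **DE test.** Welch's *t* rather than a moderated (empirical-Bayes) *t*:
  dependency-light, and with the sample sizes involved the moderation
  would mostly matter for the 5-vs-5 study. Consensus counts from real
  data will differ from any web-tool-based run for this reason.
* **Probe collapse.** When several probes map to one gene, the probe with
  the largest study-averaged |log2fc| represents the gene; probes of one
  gene with conflicting consensus directions exclude the gene and are
  logged. The rule is chosen for determinism.
* **Cox ties.** Efron's correction by default (more accurate); Breslow is
  available for replicating SPSS-based analyses, which default to
  Breslow. At the tie rates of the simulated (continuous-time) cohorts
  the difference is negligible.
* **Newton iteration.** Convergence when the largest coefficient update
  falls below 1e-7, at most 100 iterations, step-halving whenever a step
  would decrease the partial likelihood. Monotone likelihoods (perfect
  separation) are flagged `converged = FALSE` with a warning.
* **Stepwise.** Entry by the Rao score test (smallest p < `p_enter`),
  removal by a likelihood-ratio test of each included covariate with the
  reduced model actually refit (an exact version of SPSS's
  conditional-statistic approximation). Defaults `p_enter = 0.05`,
  `p_remove = 0.10` are the SPSS defaults; `p_enter <= p_remove` is
  enforced to prevent stepping cycles, and a repeated-model guard stops
  pathological loops. Candidates whose entry produces a singular or
  separated fit are dropped from consideration rather than aborting the
  run.
* **Tie-breaking at medians.** Values equal to the median go to the low
  group, so `median_split` is deterministic and order-invariant.
* **"More than half".** Signature inclusion requires selection frequency
  strictly above `freq_threshold` (default 0.5) of the successful splits;
  splits whose stepwise run fails are dropped from the denominator with a
  warning.
* **Cutpoint.** Per-split training scores are computed with the final
  averaged betas; the model cutpoint is the mean of the per-split
  training medians, and is used only for the plan's test sets. External
  cohorts are split at their own median score — matching how a signature
  is transferred across platforms — and `refit_betas = TRUE` additionally
  re-estimates the coefficients on the external cohort (both transfer
  conventions are legitimate; the package implements both and leaves the
  choice explicit).
* **"Cliques".** Operationalized as connected components of the
  positive-edge subgraph (optionally refined by greedy modularity), with
  a minimum reported size of 5; exact maximal-clique enumeration is
  NP-hard and not what correlation-heatmap figures actually display.
* **Edge multiplicity.** Bonferroni over the n(n-1)/2 unordered pairs by
  default. Note that with the default `|rho| >= 0.6` primary threshold
  the adjusted-p condition is rarely binding at realistic sample sizes;
  the correlation threshold is the scientifically meaningful filter, and
  the package reports its own adjusted-p bound rather than reproducing
  any particular published one.

## Problem sizes used by the tests

The test suite and the acceptance script run the full pipeline at sizes
chosen to make the statistical assertions sharp yet quick on a single
CPU: 795 features for the screening-threshold check; four studies with
2000 features for consensus recovery; 500–800 samples for network
recovery; a 393-patient cohort with 300/93 train/test splits, 100
candidate genes, 12 planted signature genes, and k = 20 (selection) or
k = 60 (forest) resamples. Null calibrations use 100–1000 replicates.
These sizes are the package's own choices for crisp Monte-Carlo margins;
all of them are parameters the user can raise.

One behavior worth understanding when interpreting the stability
selection results: because the k resamples draw 300 of the same 393
patients, they overlap heavily, and a null gene that is conditionally
associated with outcome *in this particular cohort* will recur across
resamples. The expected number of such stable false inclusions at the
default thresholds is small (0–3 with 100 candidates) but not zero —
stability selection controls selection noise, not cohort-level chance
association. Pre-filtering candidates by the univariate screen reduces
the candidate load but is deliberately off by default.

## Known limitations

* No time-varying covariates, stratified baselines, left truncation, or
  competing risks in the Cox kernel.
* Outcome semantics are generic time-to-event; the package does not
  distinguish relapse-free from overall survival — the user names the
  endpoint.
* Enrichment is flat-set over-representation (hypergeometric against a
  supplied GMT); no ontology hierarchy handling.
* No penalized-regression alternative to stepwise selection, and no
  soft-threshold (WGCNA-style) network mode.
* Molecular subtype labels are consumed as input, never computed.
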