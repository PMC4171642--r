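---
title: "Methods: stromal CAF signatures, risk scoring and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stromal CAF signatures, risk scoring and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

## The scientific problem

Carcinoma-associated fibroblasts (CAFs) are activated stromal cells inside a
tumour. Two properties of the stroma are easy to conflate in bulk expression
data: how *much* stroma a sample contains, and what *state* its fibroblasts
are in. stromasig implements a pipeline built around the hypothesis that the
prognostic information sits in the CAF state: genes that are deregulated
between CAFs and patient-matched normal colonic fibroblasts (NCFs) are
filtered, a small consensus signature is selected by resampling, and an
equal-weight signed z-score summarises each tumour's CAF-state signal. The
collagen score (mean standardized expression of *COL1A1* and *COL3A1*)
serves as the opposing control: a pure stromal-*quantity* proxy that should
carry no prognostic information of its own.

The published instance of this pipeline is the 5-gene colorectal-cancer
classifier (*PDLIM3*, *AMIGO2*, *SLC7A2*, *ULBP2* risk; *CCL11* protective),
with score

$$S = z_{PDLIM3} + z_{AMIGO2} + z_{SLC7A2} + z_{ULBP2} - z_{CCL11}$$

and the training-set cutoff 1.1328 (the third tertile of the training
scores). No per-gene weights are estimated: all genes carry the same
biological weight, which is what makes the score portable across platforms
after per-dataset z-scoring. The cutoff and the gene identities ship as
published constants (`published_classifier()`); they can only be re-derived
from the original training cohort, which is external data.

## Pipeline stages

1. **DEG filter** (`filter_degs`): paired two-sided t-tests on log2
   CAF-vs-NCF differences with Benjamini-Hochberg adjustment; genes must
   additionally pass a mean log2-expression floor (> 4), an SD floor
   (> 0.1), and a mean per-pair linear-scale fold change strictly above 2
   or strictly below 0.5.
2. **Eligibility** (`exclude_short_followup`): non-recurrent samples with
   less than 3 years of disease-free follow-up are removed; recurrent
   samples are always kept.
3. **Stability selection** (`stability_select`): in each of 1000 (tests:
   200) iterations the cohort is split 2:1 with stage proportionality
   (`stratified_resample`, `round(2/3 * n)` per stratum, remainder to
   test), genes are screened by univariate logistic regression of
   recurrence on expression at Wald p < 0.01 on the training split, and an
   L1-penalized logistic regression on the screened genes (10-fold
   cross-validation on the training split only, binomial deviance, penalty
   at minimum CV deviance) contributes its support. Per-iteration
   coefficients are discarded; the consensus is the set of genes selected
   in strictly more than 50% of completed iterations. The test split never
   participates in selection; its AUC is recorded for reporting.
4. **Scoring** (`zscore_genes`, `compute_score`, `derive_cutoff`,
   `classify_risk`, `score_cohort`): per-gene z-scores within a dataset,
   the signed sum, the 66.66th-percentile cutoff on training scores, and
   the high/low call (strictly above the cutoff is high).
5. **Meta-cohort pooling** (`pool_metacohort`): z-scores are computed per
   dataset *before* concatenation, removing centre/platform location-scale
   bias; provenance is retained per sample.
6. **Evaluation** (`roc_auc`, `km_logrank`, `five_year_rate`, `cox_fit`,
   `stratified_by_collagen`, `collagen_interaction`): DeLong intervals for
   AUC, two-sided unstratified log-rank tests, Cox models with Efron tie
   handling in dichotomized or per-SD continuous form, collagen-stratified
   survival and a score-by-collagen interaction.
7. **Clinical updating** (`confusion_counts`, `likelihood_ratios`,
   `posttest_probability`, `posttest_table`): LR+ = sens/(1-spec),
   LR- = (1-sens)/spec, Bayes post-test probabilities through the odds
   form, per stage stratum.
8. **qPCR support** (`fit_standard_curve`, `quantify_cq`,
   `genorm_stability`, `delta_ct_stability`, `normalize_to_references`,
   `rank_reference_candidates`): standard-curve quantification, two
   reference-gene stability measures, geometric-mean normalization, then
   log2 + per-gene z-scores feeding `compute_score`.

## The synthetic cohort generator

No public cohort ships with the package; instead `simulate_cohort()`
generates data with the statistical structure the analysis assumes, so
every stage is testable end to end. The generative model, per sample $s$
and gene $g$:

* stromal fraction $F_s \sim \mathrm{Beta}(20, 20)$ (mean 0.5, SD 0.11 --
  whole-tumour samples with moderate spread of stromal content);
* per-planted-gene CAF-state axes $A_{g,s}$ with $\mathrm{Beta}(2,2)$
  marginals and pairwise correlation $\rho = 0.45$ through a Gaussian
  copula. Each planted gene reports its own, partially independent facet
  of CAF activation; the axes are correlated because they reflect one
  underlying biological programme;
* expression $x_{g,s} = b_g + d_g\,\beta\,F_s\,(A_{g,s}-\tfrac12) +
  \varepsilon_{g,s}$ for planted genes (direction $d_g = \pm 1$, effect
  $\beta = 4$ log2 units, noise SD $0.1$); collagen genes load on $F_s$
  alone ($4 F_s$); all other genes are baseline plus noise. Baselines are
  $N(8, 1)$ on the log2 scale;
* latent risk = the standardized sum of the centred state axes;
  recurrence is Bernoulli with logit = intercept + slope $\times$ latent
  risk, the intercept calibrated so the marginal recurrence rate equals
  48/135;
* relapse times for recurrent samples are Weibull (shape 1.3, scale 24
  months) with a proportional-hazards tilt in latent risk (default log HR
  0.4/SD); follow-up is administratively censored uniformly on [36, 96]
  months, so every non-recurrent sample has at least three years of
  follow-up; disease-specific death follows relapse after an exponential
  lag.

Defaults mirror the discovery-cohort conditions: n = 135, stage II/III
about 47/53%, 108 candidate genes of which 4 + 1 are planted and 2 are
collagen, 48 recurrences.

### Two signal regimes, calibrated once

The published pipeline behaves very differently in its discovery cohort
(where resampling stability selection isolated exactly five genes out of
108) and in external validation (where the score's discrimination at the
tertile cutoff corresponds to LR+ about 2.6, i.e. an AUC near 0.7). A
single parameter set cannot reproduce both behaviours, because exact
5-of-108 recovery under a p < 0.01 marginal screen plus cross-validated
lasso at n = 135 demands far more per-gene information than an AUC-0.7
world contains. An information-budget argument makes this concrete: with
latent-risk discrimination at AUC 0.8 the total gene-outcome association
available at n = 135 is smaller than the sum of what the marginal screen
and the conditional lasso retention each require per gene, for any
generator configuration; brute-force simulation over configuration grids
confirmed recovery rates far below the target there, rising steeply with
latent discrimination.

The package therefore ships two presets, both fixed once by Monte-Carlo
calibration before the test suite was finalized and not revisited:

* `sim_params()` -- the **discovery regime**: `outcome_logit_slope = 4`,
  giving latent-risk AUC about 0.95 against recurrence. Under these
  conditions stability selection with 200 iterations recovers exactly the
  planted five genes in roughly 9 of 10 cohorts, matching the published
  discovery behaviour. Residual failures are irreducible sampling
  accidents of an n = 135 world: occasionally one of the 101 null genes
  draws a cohort-level association strong enough to clear the >50%
  consensus rule, or two planted axes draw so collinear that the lasso
  treats one gene as redundant.
* `sim_params_metacohort()` -- the **validation regime**: n = 317 with the
  stage mix of the pooled validation cohorts, prevalence 0.325, and
  `outcome_logit_slope = 1.05`, calibrated at large n so the 5-gene score
  at the tertile cutoff attains LR+ about 2.6 and LR- about 0.55, the
  published meta-cohort operating point.

### What the generator does and does not emulate

It emulates: a log2-like expression scale, stromal-quantity versus
CAF-state dissociation (collagen genes correlate with the stromal fraction
but not with recurrence), multi-dataset location-scale batch differences
(removed by per-dataset z-scoring), epithelial-enriched samples
(`simulate_epithelial_cohort` collapses the stromal fraction toward 0.01,
silencing the planted signal while the latent outcome link persists),
administrative censoring, and stage structure.

It does not emulate: probe-level microarray artefacts, correlated noise
among null genes, immune infiltration, EMT programmes, microsatellite or
*KRAS* status, non-proportional hazards, or informative censoring. Stage is
drawn independently of outcome, so covariate-adjusted models exercise
plumbing rather than confounding. Passing tests on synthetic cohorts
therefore demonstrate that the algorithms do what they claim under the
stated assumptions -- not that the published gene list would re-emerge from
real arrays.

## Numerical choices

* **Quantiles**: the tertile cutoff uses linear interpolation between
  order statistics (R type 7) at probability 0.6666; the collagen
  percentile filter uses the inverse-ECDF quantile (type 1), so that at
  the 25th percentile exactly $\lceil 0.75 n \rceil$ samples survive on
  distinct data (107 of 142).
* **Ties**: a score exactly at the cutoff is called low risk -- the
  published rule only defines strict inequalities, so the tie-break merely
  has to be deterministic.
* **Univariate screen**: a vectorized Newton-Raphson per gene with a small
  ridge (1e-4) on the information matrix, verified against `glm()`.
  (Quasi-)separation is detected from near-perfect fitted classification;
  such genes are flagged and pass with p = 0 rather than being lost to
  non-convergence. Constant genes are excluded with a warning.
* **Penalty rule**: `cv.glmnet`, 10-fold, deviance loss, `lambda.min`,
  folds drawn from the iteration's RNG stream so runs are reproducible.
* **Consensus rule**: strictly greater than the frequency threshold; at a
  threshold of 1 the rule becomes "selected in every completed iteration".
  Frequencies are computed over completed iterations, with per-iteration
  failures logged.
* **Zero-variance genes** standardize to 0 (contribution 0 to scores) with
  a warning instead of aborting a cohort.
* **Survival**: Efron ties everywhere; 95% intervals; five-year rates are
  Kaplan-Meier values at 60 months with last-value carry-forward.
  Monotone likelihood in a Cox fit triggers a ridge-stabilized refit and a
  flag.
* **Likelihood-ratio intervals** use the log-transform standard-error
  method; prevalence intervals are Clopper-Pearson exact. Post-test
  intervals propagate the LR interval at the point prevalence.
* **qPCR**: log base 2 throughout; replicate wells are averaged before
  quantification; geNorm runs on relative quantities $2^{-Cq}$ (per-sample
  factors cancel in ratios); the combined reference ranking is the
  geometric mean of the two per-method ranks. NormFinder and BestKeeper
  are not implemented; the two fully specified measures above are used.
* **Sub-streamed seeding**: one master seed feeds a named sub-stream per
  random component, so toggling one component never shifts another's
  draws.

## Open design points, resolved

* Whether the univariate screen runs on the training split or the full
  cohort is ambiguous in the source procedure; the package screens on the
  training split (the anti-overfitting reading) with
  `screen_on = "full"` available.
* The collagen score averages *standardized* collagen-gene expression by
  default (the same convention as the classifier score, and the one that
  is platform-portable); `standardize = FALSE` gives the raw average.
* The exact quantile convention behind the published cutoff 1.1328 is not
  recoverable without the original training data; the value ships as a
  constant and the package's own convention (type 7 at 0.6666) is
  documented for reproducibility of new cutoffs.

## Problem sizes used by the tests

The test-suite acceptance checks run stability selection at 200
iterations over 20 independent cohorts (and 20 null cohorts), the
epithelial negative control over 50 cohorts of n = 300, collagen-filter
monotonicity over 50 cohorts of n = 500 at filter percentiles
{0, 10, 25, 40}, and Cox per-SD recovery over 50 replicates of n = 500.
These sizes keep full runs to a few minutes while leaving the Monte-Carlo
error of each rate well below the asserted margins.

## Known limitations

* The epithelial negative-control band check asks every per-cohort AUC to
  fall inside [0.45, 0.55] at n = 300 for 95% of cohorts. The sampling SD
  of a null AUC at n = 300 with a 0.36 recurrence rate is about 0.035, so
  even a perfectly uninformative classifier lands inside that band only
  about 80-90% of the time; the per-seed version of the check is
  statistically unattainable at this n, while the mean AUC sits squarely
  at 0.5. Both quantities are reported by `scripts/acceptance.R`
  (`epithelial_auc_mean`, `epithelial_auc_in_band_rate`).
* Exact signature recovery is a stochastic property with an irreducible
  per-cohort failure rate (see above); the suite asserts the rate over 20
  cohorts, which itself carries binomial noise.
* The post-test table's interval propagation treats the prevalence as
  fixed when mapping LR intervals through Bayes; a joint interval would be
  slightly wider.

```{r example, eval = FALSE}
# A complete in-silico run of the discovery pipeline:
p <- sim_params(seed = 1)
sim <- simulate_cohort(p)
profiles <- simulate_paired_profiles(p, n_pairs = 12)
res <- stability_select(sim$cohort, stability_params(n_iterations = 200, seed = 1),
                        paired_profiles = profiles)
res$consensus
profile <- score_cohort(sim$cohort, res$consensus)
km_logrank(sim$cohort$clinical$dfs_time, sim$cohort$clinical$dfs_event,
           profile$risk_class)
```
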