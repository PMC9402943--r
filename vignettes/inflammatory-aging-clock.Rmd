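---
title: "The inflammatory aging clock: model, calibration and design choices"
author: "inflammclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The inflammatory aging clock: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflammclock)
```

## The problem and the model

Chronic low-grade inflammation accumulates with age, and in glioblastoma
(GBM) the expression of inflammation-related genes (IRG) carries both an
aging signal and prognostic information. `inflammclock` implements a
transcriptomic *inflammatory aging clock*: from a panel of roughly 200 IRG
it selects the genes whose expression tracks chronological age, combines
them into a per-patient **inflammatory age (iAge)** on the year scale, and
uses the cohort median of iAge to define high- and low-iAge molecular
subtypes whose survival is then compared.

The clock has three parts.

1. **Screening.** For every panel gene the Spearman rank correlation
   $\beta_j = \rho(X_j, \text{age})$ is computed
   (`screenAgeGenes()`); a gene enters the clock when
   $|\beta_j| \ge 0.5$ (inclusive boundary, no p-value criterion). The
   correlation doubles as the gene's weight, so positively and negatively
   age-linked genes contribute with opposite signs.
2. **Scoring.** The raw score of patient $i$ is
   $r_i = \sum_j \beta_j \tilde X_{ij}$ over the selected genes, where
   $\tilde X$ is per-gene normalized expression (min–max to $[0,1]$ by
   default; z-scoring available). The published form of the clock,
   $\text{iAge} = C \cdot \sum_j \beta_j X_j$ with $C$ "the chronological
   age", underdetermines $C$: literal per-patient multiplication of an
   arbitrarily scaled weighted sum produces unbounded scores. We make the
   calibration explicit (below).
3. **Subtyping.** Patients with iAge strictly above the cohort median are
   the high-iAge subtype (`classifyByMedian()`); ties at the median go to
   the low subtype, a deterministic and conservative rule that keeps the
   low group at least half the cohort. For distinct scores and even $n$
   the split is exactly $n/2$ / $n/2$.

## Calibration of C

Two explicit modes are implemented in `fitIAgeClock()`:

* **`cohort_constant`** (default). A shift
  $s = \max(0,\ 0.01 - \min_i r_i)$ guards against a non-positive mean
  score, and a single cohort constant
  $C = \overline{\text{age}} / \overline{(r + s)}$ maps scores to years,
  so that $\overline{\text{iAge}} = \overline{\text{age}}$ holds exactly.
  Because iAge is then a positive affine function of the raw score, all
  rankings — and in particular the median split — are identical to those
  of the raw score. This preserves the structure of the printed formula
  while yielding age-scaled, rank-faithful values.
* **`per_patient`**, a sensitivity analysis that keeps each patient's own
  age as the multiplier:
  $\text{iAge}_i = \text{age}_i\,(1 + 0.25\, z(r_i))$, with the raw-score
  standardization frozen at fit time. The scale 0.25 makes a patient two
  standard deviations above the cohort mean 50% "inflammatorily older"
  than their calendar age, which reproduces the kind of extreme
  predictions (well above 100 years for patients in their seventies) that
  an uncalibrated clock produces.

Everything needed to score a new cohort — weights, per-gene normalization
parameters, shift, constant — is frozen in the `IAgeModel` object and
serialized by `writeIAgeModel()`. External validation is a *frozen
replay*: `scoreCohort()` reuses the training parameters unchanged. Whether
the original analysis re-estimated weights in its validation cohort is not
stated; replay is the default and re-screening is available by simply
fitting on the validation cohort. Likewise, the screening cohort is an
explicit argument (the description of where correlations were estimated —
pan-cancer normal tissue versus the tumor cohort itself — is
inconsistent), and by default the same cohort is used for screening and
scoring.

## Cohort filtering

`applyInclusionFilters()` applies ordered exclusion rules, each to the
remainder of the previous one: recurrent/multifocal tumors, unknown
survival, survival below 30 days (strictly: day 29 is excluded, day 30
retained), and optional incomplete-clinical screening whose field list
defaults to `{age, time, event}` — missing optional fields never exclude a
sample unless that rule is enabled. Per-rule counts depend on the order
when predicates overlap; the retained set does not, and the counts are
conserved (`n_input = sum(excluded) + n_retained`). Times are stored in
days; tables recorded in years are converted with 365.25 days/year and
rounded to the nearest day.

## Survival machinery

The survival layer is implemented from first principles so that its
contracts are testable primitives:

* **Kaplan–Meier** product-limit estimation with Greenwood variance.
  A subject censored exactly at an event time is counted at risk for that
  time (the standard right-continuous convention); with no censoring the
  curve equals the empirical survival function exactly. Where
  $\hat S = 0$ the Greenwood standard error is reported as 0.
* **Log-rank** two-group test with hypergeometric variance at each
  distinct event time, referred to $\chi^2_1$.
* **Univariate Cox** regression maximizing the Breslow partial likelihood
  by Newton–Raphson from $\beta = 0$; convergence when the score drops
  below $10^{-8}$ or after 50 iterations; Wald 95% intervals on the
  coefficient scale. A monotone likelihood ($|\beta|$ drifting past 20,
  as with perfectly separating covariates) is flagged non-converged with
  a warning. Efron tie handling is out of scope. The per-gene prognostic
  screen z-scores each gene and flags $p < \alpha$ with **no multiplicity
  correction** by default, mirroring the study's usage; a
  Benjamini–Hochberg option exists behind `adjust = "BH"`.
* **Conditional survival** $S(t+u \mid t) = S(t+u)/S(t)$ with
  right-continuous step evaluation, and the annual table of
  $P(T > j \mid T > i)$ with the median survival defined as the first
  observed event time with $\hat S \le 0.5$ (no interpolation).

## Association analyses

`correlateStemness()` reports correlations of iAge and chronological age
with the four stemness indices (mRNAsi, EREG-mRNAsi, mDNAsi, EREG-mDNAsi)
over pairwise-complete samples; Pearson by default, Spearman optionally.
`correlationNetwork()` builds the signed gene–gene Spearman network at a
configurable threshold. `deScreen()` is the paired tumor–normal Wilcoxon
signed-rank screen with $\log_2$ fold change computed on means with a +1
pseudocount (guarding zero means) and BH q-values; significance uses
strict inequalities ($|\text{logFC}| > 1.5$, $q < 0.05$ by default — the
looser enrichment-style pair logFC $> 1$, $p < 0.05$ can be set via the
thresholds). `randomizationTest()` implements the 1,000-iteration
gene-set randomization test with the add-one p-value
$(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$; because the original
set-level statistic is not defined precisely, the statistic is an
explicit argument with two built-ins: mean absolute age-correlation of
the set (`statMeanAbsAgeCor()`) and overlap with a reference set
(`statOverlapCount()`).

## What the synthetic cohorts emulate

`generateCohort()` produces cohorts with the statistical structure the
analysis relies on, with known ground truth:

* **Ages** from a truncated normal, mean 59.23, SD 13.56 years on
  [18, 90] — the reported cohort's age distribution.
* **Age-linked genes** through a Gaussian copula: a latent bivariate
  normal with correlation $r = 2\sin(\pi\rho_s/6)$ yields population
  Spearman correlation $\rho_s$ after the monotone map to the expression
  scale ($e^z$, lognormal-like positive values). This closed form is
  exact in the population, so no lookup calibration is needed. Defaults:
  38 of 200 genes linked at $\rho_s = 0.7$, signs half positive, half
  negative.
* **Survival** from an exponential proportional-hazards model: hazard
  $0.55\,\mathrm{yr}^{-1} \cdot \exp(0.5\, z_i)$, where $z$ is the
  standardized signed sum of the linked-gene latent signals. The baseline
  reproduces a median OS near 1.26 years; the log hazard ratio 0.5 per SD
  is a moderate, detectable prognostic effect chosen once. Censoring is
  an independent exponential whose rate is solved (by `uniroot` on the
  expected censoring fraction) to hit the target 20% censoring — the
  reported cohort was 80.36% deaths.
* **Stemness indices** as monotone transforms of the negated latent
  score plus copula-calibrated noise at Spearman $-0.44$ for mRNAsi and
  mDNAsi; the two EREG indices are generated uncorrelated, matching the
  null findings reported for them.
* **Exclusion flags** (recurrent/multifocal, unknown survival) assigned
  disjointly at random with configurable fractions; a validation-style
  configuration of 388 samples with fractions 163/388 and 9/388 filters
  to exactly 216.

One seed drives a single generator stream (`withr::local_preserve_seed()`
plus `set.seed()`), so generation never perturbs the caller's RNG state.
The pipeline derives per-stage seeds by hashing the stage name
(`stageSeed()`), so inserting a stage cannot change another stage's draws.

The generator deliberately does **not** emulate RNA-seq count noise,
batch effects, gene–gene covariance beyond the shared age/score signal,
non-proportional hazards, or informative censoring. Tests passing on
these cohorts therefore demonstrate that the pipeline's machinery is
correct and well calibrated under its own assumptions — not that the
biological findings transfer to any particular tumor database.

## Numerical choices and degenerate inputs

* Spearman uses mid-ranks for ties; a constant vector yields a missing
  correlation rather than an error.
* The screening boundary $|\beta| \ge$ threshold is evaluated with
  $10^{-12}$ slack so a correlation equal to the threshold in exact rank
  arithmetic is not lost to floating-point rounding.
* Constant genes normalize to 0.5 (min–max) or 0 (z-score); an
  all-identical raw-score vector is an error in cohort-constant mode
  because no ranking exists.
* Median-split ties go to the low subtype; an all-identical iAge vector
  is an error.
* The add-one permutation p-value is never exactly zero; an all-zero
  difference vector in the Wilcoxon screen gets $p = 1$.

## Problem sizes

The test-suite and acceptance-script simulations use cohorts of 60–500
samples over 200-gene panels, 20 replicate seeds for operating
characteristics (screening sensitivity/false selection, Cox recovery,
clock validity, stemness association) and 2,000 replicates for the
log-rank type-I-error check — sizes at which the binomial/Monte-Carlo
error of each checked quantity is comfortably below the asserted margins.

## Worked example

```{r example, eval = FALSE}
co <- generateCohort(simConfig(seed = 1))
model <- fitIAgeClock(co)
iage <- scoreCohort(model, co)
sub <- classifyByMedian(iage)
cl <- clinicalData(co)
logrankTest(cl$survival_time_days / 365.25, cl$event, sub$subtype)

# frozen replay on a validation-style cohort
val <- generateCohort(simConfig(nSamples = 388,
                                fracRecurrentOrMultiple = 163 / 388,
                                fracSurvivalUnknown = 9 / 388, seed = 2))
kept <- retainSamples(val, applyInclusionFilters(
  clinicalData(val), c("recurrent_or_multiple", "survival_unknown")))
scoreCohort(model, kept)
```

## Known limitations

* The clock's weights are marginal rank correlations, not a sparse joint
  fit; collinear genes are double-counted by design, exactly as in the
  published construction.
* The cohort-constant calibration fixes only the first moment of iAge;
  the spread of iAge in years depends on the spread of the weighted score
  and is not separately calibrated.
* The survival layer is univariate: no multivariable Cox, time-dependent
  covariates, or competing risks.
* Stemness indices are consumed as inputs; computing them from expression
  or methylation data is out of scope.
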