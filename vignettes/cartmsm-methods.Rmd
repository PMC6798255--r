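---
title: "Methods: weighted comparative effectiveness of cART regimens"
author: "cartmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted comparative effectiveness of cART regimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartmsm)
```

## The estimation problem

Semiannual-visit HIV cohorts observe, at each visit, the self-reported
antiretroviral regimen, laboratory values (CD4 count, HIV RNA), and a panel
of clinical and behavioural covariates. Three binary outcomes summarize how
well a regimen works in practice over a pair of consecutive visits
$(V_i, V_{i+1})$ no more than a year apart:

* **switching** — the drug-code *set* at $V_{i+1}$ differs from that at
  $V_i$, or ART was discontinued;
* **adherence** — 100% self-reported use of every prescribed drug over a
  4-day recall at $V_{i+1}$, defined only when the same regimen was used at
  both visits;
* **suppression** — HIV RNA strictly below 20 copies/mL at $V_{i+1}$, on the
  same same-regimen population as adherence (50 copies/mL for the long-run
  trend series, to accommodate older assays; assay-floor readings count as
  suppressed when the floor is at or below the threshold).

Because prescribing responds to prognosis (channeling), regimen groups
differ systematically in CD4, detectable RNA and comorbidity; because those
covariates also respond to earlier treatment, they are simultaneously
confounders and mediators, and conditioning on them in an outcome regression
is not a valid correction. Dropout correlated with health state adds
informative censoring. The package addresses both with stabilized
inverse-probability-of-treatment-and-censoring (IPTC) weighting and fits the
marginal structural model (MSM)

$$\log E\,[Y_i \mid R_i = r, V, H_{i-1}] = \beta_0 + \beta_r + \gamma' V +
\delta' H_{i-1},$$

where $V$ are time-fixed covariates (age spline, group), $H_{i-1}$ is
treatment history (previous regimen), and $\exp(\beta_r)$ is the rate ratio
of regimen $r$ against the reference — the most reported regimen, so that
contrasts read as "versus the standard single-pill NNRTI regimen".

## Stabilized IPTC weights

For each analysis visit $k$ of a person, the treatment factor is
$p^T_{num}(k)/p^T_{den}(k)$: both are the fitted probability of the regimen
*actually received*, from a 7-category baseline-logit multinomial model. The
numerator model contains treatment history and time-fixed covariates only;
the denominator adds the time-varying confounders (CD4 category, detectable
RNA, comorbidity score). The censoring factor $p^C_{num}(k)/p^C_{den}(k)$
comes from two nested logistic models for remaining uncensored, fitted on
the risk set of visits whose previous visit was observed, with predictors
from the previous visit. The stabilized weight of an analysis row is the
within-person cumulative product of the factors from the start of the
analysis window through $V_i$, times the censoring factor for reaching
$V_{i+1}$ (where the outcome is ascertained).

Design choices, made once and used everywhere:

* **Cumulative weights with window-start reset.** Weights multiply over the
  visits inside the analysis window; history before the window enters the
  models as covariates rather than as weight factors. A per-visit
  (non-cumulative) mode is available as a sensitivity switch
  (`cumulative = FALSE`).
* **Truncation at the pooled 1st/99th percentiles** of the final weights
  (`truncate_weights()`), the standard guard against a few extreme weights
  dominating the fit. At the reference conditions this clamps almost
  exactly 2% of rows; the bounds actually used are reported. Truncation
  trades a small bias for variance; the balance diagnostics below use raw
  weights for exactly that reason.
* **Probability floors at 1e-12** before any division, with floored rows
  counted and reported.
* **Diagnostics.** `weight_diagnostics()` reports the mean (which must be
  near 1 for stabilized cumulative weights), spread and percentiles;
  `weighted_smd()` reports weighted standardized mean differences of the
  confounders across regimen groups — under a correctly specified
  denominator model with marginal stabilization these vanish.

## Modified Poisson regression with cluster-robust variance

Rate ratios for binary outcomes come from `modpois()`: a log-link Poisson
pseudo-likelihood fit whose sandwich covariance clusters scores at the
person level, because persons contribute several overlapping visit-pairs.
The small-sample multiplier $G/(G-1)$ is applied to the cluster-summed
"meat". With singleton clusters this is the ordinary robust
(heteroskedasticity-consistent) estimator, and the implementation is
cross-checked in the test suite against an independent computation from the
`sandwich` package and against a nonparametric cluster bootstrap.

Inference conventions: IRLS convergence is declared when the relative
deviance change falls below 1e-10 (at most 100 iterations), any
coefficient exceeding 15 in absolute value raises a separation flag and a
warning (never a silent ridge), and rank-deficient designs are an error
naming the aliased columns. Confidence intervals are Wald intervals on the
log scale using the robust standard errors. The sandwich treats the
estimated weights as fixed; accounting for weight estimation would typically
*shrink* the intervals, so the reported intervals are conservative in the
usual direction.

## Restricted quadratic spline for age

Age enters every model through a restricted quadratic spline with 4 knots at
the 20th, 40th, 60th and 80th percentiles of the cohort age distribution
(type-7 sample quantiles, i.e. linear interpolation of order statistics).
The basis is $x$ together with

$$s_j(x) = \frac{(x-k_j)_+^2 - (x-k_4)_+^2}{k_4 - k_1}, \qquad j = 1, 2,$$

omitting the third truncated term so the fitted curve is linear below
$k_1$ and above $k_4$ with a continuous first derivative throughout — a
3-column basis for 4 knots. Stratified analyses dichotomize raw age at 50
years at the index visit; the spline operates inside the weight and outcome
models only.

## Multiple imputation

Missing covariates and outcomes are imputed under a joint multivariate
normal model estimated by EM over arbitrary missingness patterns
(`fit_mvn_model()`), with binary variables carried on the 0/1 scale.
Imputation is *proper*: each of the $m = 25$ completed datasets draws
$\mu^* \sim N(\hat\mu, \hat\Sigma/n)$ and
$\Sigma^* \sim \mathrm{Wishart}(n-1, \hat\Sigma/(n-1))$ — a normal/Wishart
approximation to the sampling distribution of the EM estimates, chosen over
full data augmentation for determinism and desk-scale cost — and then draws
each missing block from its conditional normal given the observed entries.
Binary targets are thresholded at 0.5. The entire pipeline (weights plus
outcome models) is re-run on every completed dataset and the per-imputation
log rate ratios are combined by Rubin's rules: pooled estimate = mean;
$T = \bar W + (1 + 1/m)B$; degrees of freedom
$(m-1)\,(1 + \bar W/((1+1/m)B))^2$. With nothing missing the pipeline
collapses exactly to the complete-data analysis.

## The synthetic cohort and its oracles

`simulate_cohort()` generates the structure the estimator is built for, with
all true effects configurable:

* semiannual visits (up to 6) from 2014 onwards; 7 regimen categories with
  a strong stickiness bonus for staying on the previous regimen, so
  switching rates land near observed cohort levels (~15%);
* **channeling**: sicker states (low CD4, detectable RNA, high comorbidity)
  raise the odds of the boosted-PI regimens and lower those of the newer
  INSTI single-pill regimens;
* **treatment–confounder feedback**: the comorbidity score is
  autoregressive, responds to the previous regimen, and loads on a bounded
  latent frailty that also multiplies outcome risk — so past treatment
  shapes a variable that predicts both future treatment and dropout, and
  correlates with outcomes through the frailty;
* **informative, absorbing dropout** from a logit on the previous visit's
  state (the cohort's "remaining uncensored" structure: no re-entry);
* **outcomes** as Bernoulli draws from a log-linear risk: intercept +
  current-regimen effect + CD4/RNA effects + age + group + frailty, so the
  configured regimen coefficients *are* rate ratios. Configurations that
  could push any risk to 1 or above are rejected at validation, never
  clipped. Default switching effects span 0.12–1.8 across regimens; default
  missingness rates (3% adherence, 6–13% covariates, up to 24%) mirror the
  ranges reported for cohort questionnaires and laboratory panels.

Two deliberate design decisions make the generator a sharp oracle rather
than just a stress test. First, CD4 and detectable RNA evolve exogenously to
treatment (a stationary latent AR(1) and a logit on CD4): they confound
(they drive both prescribing and outcomes) but are not treatment-mediated,
while the feedback channel runs through the comorbidity score, which does
not enter the outcome risk directly. Second, the outcome model is log-linear
with no treatment–covariate interactions. Together these give exact
log-link collapsibility: the marginal "always-$r$ versus always-reference"
rate ratio equals the configured $\exp(\beta_r)$, the current-regimen MSM is
exactly correctly specified, and the IPTC-weighted estimator is consistent
for the g-computation truth — so any systematic discrepancy in validation is
an implementation bug, not an estimand mismatch. The crude association, by
contrast, is biased by design (about +0.15 log units for the boosted-PI
regimens, negative for the INSTI regimens at the default settings).

`true_marginal_rr()` computes the marginal truth by Monte-Carlo
g-computation: the dynamics are simulated with the regimen forced to $r$ at
every visit versus forced to the reference (common random numbers across
arms, dropout disabled), and the mean event probabilities over the analysis
visits are compared; the paired delta-method Monte-Carlo standard error is
returned. `true_crude_rr()` simulates the observational regime (channeling
and dropout active) and returns the estimand of the naive estimator with a
person-clustered standard error. Determinism: a single seed feeds one
row-major uniform stream with a fixed per-person draw budget, so results are
bit-reproducible and the draws of person $j$ do not change when the cohort
is enlarged.

What the generator does **not** emulate: pharmacokinetics, resistance
evolution, drug-level adherence dynamics, or calibration to any real
cohort's marginal distributions; the outcomes are independent Bernoulli
draws given the state, not consequences of the simulated regimen path (so
the "switching" outcome is an outcome *about* switching behaviour with
known effects, not the path's own transitions). The strength of the
censoring mechanism is a modelling choice made for testability (roughly
7–15% per-visit dropout), as no external value pins it down. Passing
validation on this generator therefore demonstrates correctness of the
estimation machinery under the model's assumptions, not robustness to the
many ways real cohort data violate them.

## Validation design and problem sizes

The test suite validates each layer against an independent oracle: exact
closed forms (two-group proportion ratio; 2×2 logistic; the Rubin triple on
a three-imputation worked example), an independent optimizer for the
multinomial likelihood, the `sandwich` package and a 1,000-resample cluster
bootstrap for the robust covariance, sort-based order-statistic oracles for
percentile knots and truncation bounds, finite differences for the spline's
$C^1$ property, and the g-computation oracles for end-to-end causal
recovery. Problem sizes were chosen so each check has the power it needs at
desk scale: the recovery study uses 5,000 persons × 6 visits with oracle
truths at $10^5$ Monte-Carlo persons; the null-calibration study uses 200
replicates of 1,000 persons; balance properties use 3,000–5,000 persons;
the MI coverage study uses 200 replicates of 300 observations with
$m = 25$.

Two behaviours deserve explicit notes. The weighted analyses of adherence
and suppression condition on regimen persistence across the pair (the
defining eligibility of those outcomes); persistence is itself an outcome of
the treatment process, so these estimands carry a selection component that
the weights do not remove — a property of the design being emulated, not of
the implementation. And per-regimen 95% interval coverage in the
null-calibration study runs slightly below nominal (roughly 93–95%) for the
rarer regimens, the familiar small-sample behaviour of Wald log-rate-ratio
intervals with tens of events; with 200 replicates the binomial noise of the
coverage estimate itself is about ±1.5 percentage points, which should be
kept in mind when reading any single category's coverage figure.

## Degenerate inputs and numerical conventions

Empty treatment categories, rank-deficient designs, all-zero outcomes,
constant variables in the MVN model, non-distinct percentile knots and
negative laboratory values are all errors that name the offending
column/category; separation is a flagged warning. Assay-floor RNA readings
are treated as below-limit for suppression and as the limit value for
numeric use (standard left-censoring convention). "Within one year" is
implemented as ≤ 365 days. Regimen equality is set equality of canonical
drug codes after alias resolution, so drug order, case and brand naming
never matter. The unadjusted comparison model is regimen-only by default,
with a covariate-adjusted unweighted variant available
(`unadjusted = "covariate_adjusted"`); forcing all weights to 1 reproduces
the unweighted analysis exactly, which the suite asserts.
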