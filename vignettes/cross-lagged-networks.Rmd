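---
title: "Cross-lagged panel networks for executive function and psychopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for executive function and psychopathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
library(dplyr)
```

## The question and the model

Do executive-function (EF) deficits in adolescence *precede* psychopathology
(the risk-factor account) or *follow from* it (the consequence account)?
Cross-lagged panel network (CLPN) analysis addresses this without choosing
predictors and outcomes a priori. The network has five nodes measured at each
wave: internalizing symptoms, externalizing symptoms, working memory, and the
speed and accuracy components of inhibitory control. For a pair of adjacent
waves $(t, t+1)$, each node $j$ at wave $t+1$ is regressed on *all* nodes at
wave $t$:

$$
y_j^{(t+1)} = \beta_{0j} + \sum_{i=1}^{p} \beta_{ij}\, y_i^{(t)}
            + \gamma_j\, \mathrm{age}^{(t)} + \varepsilon_j ,
$$

estimated with the LASSO penalty $\lambda_j \sum_i |\beta_{ij}|$ so that weak
coefficients are exactly zero. Off-diagonal $\beta_{ij}$ are cross-lagged
edges, diagonal ones autoregressive edges. Age (and optionally gender) enters
every regression as a predictor but is never itself a target, so covariates
have zero incoming edges by construction. Each regression's penalty is chosen
by 10-fold cross-validation. Because the node-wise regressions are estimated
wave pair by wave pair, the two networks (waves 1→2, 2→3) can differ — which
is exactly the developmental question.

A directed EF→symptom edge supports the risk-factor account for that pair of
constructs; a symptom→EF edge supports the consequence account; both edges
mean both processes operate; neither means no direct temporal link at this
resolution. `classify_accounts()` encodes this mapping from the signed
support pattern; labels are presence-based, with the two directed weights
carried as evidence.

## Why a synthetic-cohort generator is first-class here

The motivating cohort design — three waves at mean ages 10.20, 13.48 and
18.20, strong oversampling of children at high familial risk (60.89% of the
sample), and 35.14% attrition that is *informative* (higher wave-1
internalizing predicts a *lower* probability of dropout) — involves licensed
data that cannot be redistributed. `simulate_cohort()` therefore generates
cohorts with exactly that statistical structure and a *known* sparse
cross-lagged coefficient matrix, so that every downstream stage can be
validated against ground truth.

The generator is latent-then-measure: latent node scores follow
$z^{(t+1)} = B_t^\top z^{(t)} + a\,\mathrm{age} + \eta$ (with spectral radius
of $B_t$ checked $< 1$), and observed scores are produced by a measurement
model. The latent layer is not something the analysis model sees; it exists
so that indicator aggregation and orientation rules can be tested against
truth. Measurement realism includes:

* two backward-span indicators (digit, corsi) loading on latent working
  memory, with indicator noise calibrated *per wave against the realized
  latent variance* so their correlation matches the configured target of
  0.46 — a plain fixed noise variance would overshoot the correlation under
  high-risk oversampling, which inflates latent variance;
* go/no-go summaries: mean correct-go RT (ms), decreasing in latent speed,
  and commission errors drawn binomially over the task's 25 no-go trials
  with error probability decreasing in latent accuracy;
* CBCL broad-band raw scores with instrument-specific scales, the adult
  (ABCL) instrument assigned to wave-3 records of participants aged ≥ 18;
* span scores kept continuous (integer rounding would attenuate the
  indicator correlation below its target, and the analysis standardizes
  them anyway).

The high-risk group receives configurable mean shifts (default +0.6 z on
symptoms, −0.2 to −0.3 z on cognition) applied fully at wave 1 and at 30%
strength on later-wave innovations, so group contrasts persist across waves
instead of decaying geometrically under autoregression. Risk acts through
means only — no group-specific dynamics. Gender is an independent binary
covariate with zero true effects.

Attrition is a single event per participant: dropout probability
$\mathrm{logit}^{-1}(\beta_0 + \beta_I z_{I,1})$ with $\beta_I = -0.35$ by
default, the intercept solved numerically so the marginal rate equals the
target (0.3514). The dropout wave is 2 or 3 with equal probability and
missingness is monotone; the cohort literature reports only the aggregate
loss, so this is the simplest mechanism matching it.

What the generator does *not* emulate: site effects, item-level symptom
scales, non-monotone (returning) dropout, floor/ceiling effects in spans,
and practice effects beyond smooth wave trends. Passing tests therefore
demonstrate correctness of the estimator and pipeline under a realistic but
idealized data-generating process, not performance guarantees on any real
cohort.

## Preprocessing rules

`preprocess_panel()` applies, in order: single-pass outlier removal on the
go/no-go summaries (|z| ≥ 4, computed per variable per wave — a single pass
because iterating would remove points beyond the stated rule; per wave
because task distributions shift substantially across adolescence);
negation of RT and commission errors so higher always means better
inhibitory control; z-standardization and averaging of the two backward
spans into one working-memory composite (a participant missing either
indicator gets a missing composite — no single-indicator fallback);
within-instrument z-scoring of CBCL/ABCL scales so both instruments enter on
a common scale; complete-case inclusion on the wave-1 measures (plus
non-missing wave-3 symptoms for the waves 2→3 analysis); and per-wave
z-scoring of the five nodes on the analysis sample. There is no imputation.
Every mean/SD used is recorded in the report, and `replay_preprocess()`
reproduces the processed table bit-for-bit from the raw input — the audit
guarantee for the transformation.

## The solver and its numerical choices

The node-wise LASSO is solved by cyclic coordinate descent written for this
package (C++ core): zero initialization, fixed cyclic order, warm starts
along a 100-point log-spaced penalty path from $\lambda_{\max}$ (the smallest
penalty with empty support) down to $10^{-3}\lambda_{\max}$. Convergence is
declared when the largest coefficient update in a sweep falls below $10^{-8}$
on the standardized scale; non-convergence raises a typed error carrying the
last iterate. Predictors are standardized globally on the wave-pair analysis
sample before cross-validation (fold-wise restandardization inside the CV
loop is handled by the solver's internal centering, and coefficients are
always reported back on the globally standardized node scale, so edges are
comparable across targets). Tests verify the orthonormal-design closed form,
the $\lambda = 0$ least-squares limit, KKT stationarity, agreement with an
independent box-constrained quadratic-programming solution, and agreement
with glmnet on shared grids.

### Penalty selection: CV-min versus one-SE

The default rule is the cross-validation minimum. It is deliberately
liberal: it maximizes predictive fit and yields the dense networks this
method reports in practice, but on simulated data its false-edge rate is
substantial (measured specificity ≈ 0.5 at $n = 1500$ with default
measurement noise, partly because measurement error makes some true-zero
observed-scale partial coefficients genuinely nonzero). The one-SE rule
(`rule = "one_se"`) is the documented sparser alternative: in the package's
recovery experiments at $n = 1500$, $|\beta| = 0.3$, it detects ~99% of true
edges while keeping the false-edge rate near 1%. Users who interpret
individual edge presence should prefer one-SE or a bootstrap inclusion
filter; users who interpret the weighted network as a predictive summary can
keep CV-min. Fold assignment is a seeded uniform partition without
stratification.

## Bootstrap edge accuracy

`bootstrap_network()` resamples whole participants with replacement (same
$n$), preserving the panel structure, and refits the entire estimation
stage — standardization, penalty path, CV selection, LASSO — on each
replicate, treating penalty selection as part of the estimator being
assessed. Per-edge summaries are the resampling mean, SD, 2.5/97.5
percentile interval and the inclusion proportion (fraction of replicates
with a nonzero weight). Percentile intervals are used rather than BCa: they
are standard in the bootstrap-for-networks methodology and directly
verifiable. Failed replicates are skipped and counted; more than 10%
failures aborts.

## Evaluation conventions

Network density is the proportion of nonzero cells in the 5×5 lagged matrix,
autoregressive diagonal included and covariate rows excluded — the only
convention under which reported densities of 72% and 92% correspond to
integer edge counts (18/25 and 23/25) on a five-node network; this
convention is recorded in the run manifest. "Nonzero" is exact — the LASSO
produces exact zeros, so no epsilon threshold is applied.
`compare_networks()` reports densities, support Jaccard overlap, weight
correlation and sign flips; no formal network-difference test is attempted.

## Problem sizes used in validation

The package's own simulation studies (tests and the reproduction script)
use: calibration checks at $n = 10{,}000$ (one cohort simulates in well
under a second); support-recovery at $n = 2000$ with 100 replications
(sensitivity and sign accuracy of detected edges under CV-min); null
cohorts at $n = 500$ with 100 replications (median selected lagged support
per node ≤ 1); and bootstraps at $b = 200$ with $n = 2000$ (inclusion
saturation for a $|\beta| = 0.8$ edge) and $n = 300$ (all-noise intervals
covering zero). Production analyses should use $b = 1000$, the default.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_participants = 2000, seed = 1)
panel <- simulate_study(cfg)          # cohort + informative attrition
pp <- preprocess_panel(panel)
net12 <- fit_clpn(pp$data, c(1, 2), seed = 1)
net23 <- fit_clpn(pp$data, c(2, 3), seed = 1)
compare_networks(net12, net23)
classify_accounts(net23)
bs <- bootstrap_network(pp$data, c(2, 3), b = 1000, seed = 2)
summarize_edges(bs, net23)
autoplot(net23); autoplot(bs, net23)
```

## Known limitations

* Complete-case estimation per wave pair (listwise); attrition is handled by
  inclusion rules, not FIML or imputation, matching the preprocessing rules
  implemented here.
* No contemporaneous (within-wave) network, no partial-correlation model,
  no SEM-based panel VAR: the between-wave-pair comparison is descriptive.
* Coefficients are on the observed, standardized scale; with noisy measures
  they are attenuated relative to latent dynamics, which is intrinsic to the
  observed-score design and visible in the package's recovery experiments.
* The generator's wave trends and symptom scale parameters are plausible
  defaults, not estimates from any specific cohort table.
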