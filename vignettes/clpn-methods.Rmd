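---
title: "Cross-lagged panel networks for dichotomous symptom items: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for dichotomous symptom items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`clpnet` estimates directed temporal networks among binary symptom items —
the setting of dichotomous depression screeners such as the CES-D-8
administered across panel waves. For a wave pair $(t, t+1)$ and items
$j = 1, \dots, p$, each item at the later wave is regressed on *all* items
at the earlier wave with L1-penalized logistic regression:

$$\operatorname{logit}\,P\!\left(x_j^{(t+1)} = 1 \mid x^{(t)}\right)
  = c_j + \sum_{i=1}^{p} B_{ij}\, x_i^{(t)},$$

estimated node-wise by minimizing the mean negative Bernoulli
log-likelihood plus $\lambda_j \sum_i |B_{ij}|$ (intercept unpenalized).
The coefficient matrix $B$ is the network: the diagonal $B_{jj}$ holds
autoregressive paths (a symptom predicting itself), off-diagonal entries
$B_{ij}$ are cross-lagged paths (symptom $i$ predicting symptom $j$ one
wave later, adjusted for every other symptom and for $j$'s own
autoregression). Weights live on the log-odds scale; `to_odds_ratios()`
gives the $e^{B_{ij}}$ view in which 1 means "no edge", values above 1
positive and below 1 negative connections. The LASSO's soft threshold
shrinks small coefficients exactly to zero, so the estimated network is
sparse by construction.

This is a between-wave, population-level model: it cannot separate
within-person from between-person dynamics, and it conditions only on the
immediately preceding wave (first-order Markov in the wave index).

## Estimation choices

**Solver.** Each node-wise problem is solved by a proximal-Newton
coordinate-descent algorithm (Rcpp): iteratively reweighted least squares
with the intercept absorbed by weighted centering, coordinate descent on
the resulting quadratic with lazily materialized Gram columns, and
objective-based step halving so the penalized objective is monotone even
when quasi-separation floors the IRLS weights. Convergence is declared
when no parameter moves more than `tol` (default `1e-7`). At
$\lambda = 0$ the solver agrees with Newton-IRLS (`glm`) to well below
`1e-4` per coefficient; at $\lambda > 0$ it matches `glmnet` at matched
penalties to about `1e-8` (both are cross-checked in the test suite).
Exactly collinear predictors are refused at $\lambda = 0$ — an honest
failure instead of a silent pseudo-inverse — while any positive penalty
resolves them.

**Penalty selection.** Per outcome, $\lambda_j$ is chosen by 10-fold
cross-validation over a 100-point log-spaced path from $\lambda_{\max}$
(the smallest penalty that zeroes every penalized coefficient) down to
$10^{-3}\lambda_{\max}$, minimizing the fold-averaged out-of-fold binomial
deviance (`cv_min`, the default). Folds are stratified by outcome class
and seeded; exact ties go to the larger (sparser) penalty. The `cv_1se`
mode instead takes the largest penalty within one standard error of the
minimum. The two modes trade error types against each other: on the
package's synthetic fixtures (quantified by the validation suite and
`scripts/acceptance.R`), `cv_min` recovers every true edge of magnitude
$\geq 0.4$ log-odds at $n = 7000$ sign-correctly with true-vs-estimated
correlation above 0.9, at the price of a non-trivial number of weak
spurious cross-lagged edges on null panels — the behavior of
minimum-deviance CV generally, as it also matches `cv.glmnet`'s
`lambda.min` selection per outcome. `cv_1se` is markedly more
conservative on null data but shrinks true moderate (≈0.4) edges to zero
at the same sample sizes. We keep `cv_min` as the default because the
dense networks reported for real panel data are consistent with
minimum-deviance selection and because missing a true moderate edge is
usually the costlier error in descriptive network analysis; switch to
`cv_1se` when false edges are the greater concern.

**Other fitting defaults.** Predictors are left unstandardized: all items
are 0/1 on a common scale and rescaling dummies would distort the
odds-ratio reading of the weights (a `standardize_predictors` flag
exists). The autoregressive coefficient is penalized like any other
(`penalize_autoregressive = FALSE` exempts it). Reverse-keyed (positively
worded) items are recoded toward the construct before fitting
(`direction_convention = "recode_reverse_first"`), so every edge reads as
symptom-to-symptom influence; `"raw"` mode fits items as stored, in which
case positively worded items produce negative associations with symptom
items — useful when replicating analyses that kept the raw coding, and
used throughout our recovery tests so the estimand is the generative
matrix itself.

## Centrality

Out-expected influence of item $i$ is $\sum_{j \neq i} B_{ij}$ — how much
a symptom predicts the other symptoms at the next wave; in-expected
influence of $j$ is $\sum_{i \neq j} B_{ij}$. Sums are taken on the
log-odds scale, not the odds-ratio scale: log-odds give an absent edge a
contribution of exactly 0, whereas sums of odds ratios have no meaningful
zero point. Autoregressive paths are excluded by default
(self-prediction is not inter-symptom influence; a flag includes them).
Both indices are also z-standardized within network for display; the two
raw vectors always share the same total (the off-diagonal sum of $B$), a
conservation identity the tests enforce at machine precision.

## Bootstrap diagnostics

*Edge accuracy*: nonparametric bootstrap — persons resampled with
replacement, the network refit per resample, percentile intervals per
edge (BCa intervals are deliberately not used; percentile intervals are
cheap, transparent and standard in this literature). Resamples in which
an outcome item becomes single-class are redrawn, up to ten consecutive
attempts.

*Centrality stability*: case-drop bootstrap — for each drop proportion
$p$ in a grid (default 0.10–0.75 by 0.05), subsamples without replacement
retaining $(1-p)N$ persons, correlating subsample expected influence with
the full-sample values. The CS-coefficient is the largest $p$ whose 5th
percentile correlation still reaches 0.70 (threshold and quantile
configurable; values follow the convention of the bootnet literature).

*Difference tests*: two edges (or two items' centralities) differ
significantly when the percentile interval of the bootstrap distribution
of their difference excludes zero. **No multiple-testing correction is
applied** — the convention in the symptom-network literature — so families
of such tests must be read descriptively.

By default the penalty is re-selected by CV inside every resample (honest
variability). `freeze_lambda = TRUE` reuses the full-sample per-outcome
penalties, trading a small understatement of selection variability for an
order-of-magnitude speedup; the package's own stability and type-I
experiments use the frozen mode at problem sizes of 100 replications ×
200 resamples (type-I of the edge difference test, which the acceptance
script reports against its nominal 5% level) and 100 subsamples per drop
proportion (case-drop curves).

## Synthetic panels: what they emulate and what they do not

The generator draws wave 1 independently per item as
Bernoulli($\pi_i$) and propagates later waves through the same logistic
transition law the estimator targets, so every downstream stage has exact
ground truth. The default 8-item fixture mimics a dichotomous CES-D-8
panel: endorsement probabilities (0.12, 0.20, 0.36, 0.92, 0.12, 0.91,
0.20, 0.20) with the two positively worded items near 0.9;
autoregressive weights 1.2; twelve cross-lagged edges between 0.4 and 0.9
log-odds concentrated on the somatic-drive items (effort ↔ could-not-get-
going), the positively worded pair, and loneliness → depressed-affect
paths, echoing the strongest edges reported for older-adult panel data.
Transition intercepts are calibrated by exact enumeration over predictor
states (Monte Carlo above 12 active predictors) so later waves hold the
wave-1 prevalences; the calibration residual is below $10^{-4}$.

Missingness is overlaid at the person-wave level (whole interviews, the
dominant pattern in panel attrition): at waves $\geq 2$ an interview goes
missing with probability
$\operatorname{logit}^{-1}(m_0 + m^\top \text{aux} + m_s \cdot
\text{sum}_1)$. The defaults ($m_0 = -1.5$, white $-0.5$, female $-0.1$,
$m_s = 0.15$) give roughly 10–20% per-wave dropout that is more likely
for non-white respondents and for higher wave-1 symptom loads —
missing-at-random by construction, since the draw happens before any
later-wave value exists.

Known departures from real data, hence limits on what green tests show:
wave-1 items are drawn independently (no baseline cross-sectional
dependence), the transition law is exactly the fitted model (no
model misspecification), aux covariates are two Bernoulli indicators, and
missingness is never not-at-random. Passing recovery tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to violations of them.

## Imputation

`chained_impute()` is a minimal chained-equations single imputer for
binary items: missing cells start as draws from each column's observed
marginal; for `n_cycles` (default 10) each incomplete item-wave column is
regressed by unpenalized logistic regression on all other item-wave
columns plus the auxiliary covariates, and its missing cells are re-drawn
as Bernoulli(fitted probability). Observed cells are never altered, and
imputed values are stochastic draws rather than rounded probabilities so
binary marginals are preserved. One completed dataset is produced —
analyses here run on a single imputation, with `complete_cases()` as the
sensitivity counterpart — and users wanting multiple imputations can loop
over seeds, though pooling is out of scope. Separation in a conditional
model (e.g. a near-deterministic predictor) leaves finite, perfectly
predictive coefficients and is used as-is; only genuinely broken fits
(errors, non-finite or aliased-and-unfixable coefficients) fall back to a
marginal draw with a warning. The number of cycles and the
full-conditional predictor set are declared defaults, not estimates:
standard chained-equation practice.

## Descriptives

For a dichotomous item with endorsement probability $p$, skewness and
excess kurtosis have closed forms, $(1-2p)/\sqrt{p(1-p)}$ and
$(1-6p(1-p))/(p(1-p))$; the package uses these population forms (not
sample-adjusted estimators) because published item tables for dichotomous
scales reproduce under them. Internal consistency uses KR-20 — Cronbach's
alpha specialized to binary items — with population variances throughout.
Wave-to-wave sum-score changes use the classical paired *t*-test from
`stats`.

## Numerical and degenerate-input policy

Responses must be coded strictly 0/1; other numeric values are refused,
never coerced. Constant outcome items, all-missing columns, zero-variance
centrality or edge vectors, and $p \in \{0, 1\}$ moments raise errors
naming the offender. At $\lambda \geq \lambda_{\max}$ the fit returns the
closed form (empty network, intercepts at the outcome logits) exactly.
Degenerate z-standardization (zero spread) reports zeros plus a flag.
CV ties break toward the sparser model; bootstrap and simulation seeds
make every stochastic result bit-reproducible.

## Problem sizes used in the validation suite

Recovery runs at $n = 7000$ (3 seeds), null-sparsity at $n = 5000$
(10 seeds), the type-I experiment at $n = 1200$ with 200 frozen-penalty
resamples and 100 replications, and case-drop stability at $n = 5000$
with 100 subsamples per proportion. These sizes were chosen to mirror the
order of magnitude of real ageing-panel samples while keeping the full
validation suite runnable on a laptop in well under half an hour.
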