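---
title: "Population-adjusted indirect comparisons: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-adjusted indirect comparisons: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popadjust)
```

## The problem

A common situation in health technology appraisal: a manufacturer holds
individual patient data (IPD) for its own randomized AB trial, but only
published aggregate data for a competitor's AC trial — per-arm sample
sizes and summary outcomes, plus marginal covariate summaries (means and
SDs for continuous covariates, proportions for binary ones). The decision
problem needs the B-versus-C contrast, $d_{BC}$, in an explicitly stated
target population.

A standard (Bucher) indirect comparison forms, on a chosen linear
predictor scale with link $g$,

$$\hat\Delta_{BC} = \hat\Delta_{AC}(AC) - \hat\Delta_{AB}(AB), \qquad
\hat\Delta_{AB}(AB) = g(\bar Y_B^{(AB)}) - g(\bar Y_A^{(AB)}),$$

which is unbiased only when every *effect modifier* — a covariate that
changes the relative effect on that scale — has the same distribution in
the two trial populations. With effect modification, conditional relative
effects take the additive form $d_{AB}(x_{EM}) = d_{AB}(0) +
\gamma^\top x_{EM}$, so the population-average effect moves with the
effect-modifier means, and the naive comparison is biased by
$\gamma_B^\top(\mathbb E[X_{EM}\mid AC] - \mathbb E[X_{EM}\mid AB])$
(for $\gamma_C = 0$).

Two population-adjustment families use the AB IPD to predict what the AB
arms would have shown in the AC population.

## MAIC: matching-adjusted indirect comparison

Each AB patient receives a weight equal to the estimated odds of
enrollment in AC versus AB, log-linear in the matched covariate moments:
$\log w_i = \alpha_0 + \alpha_1^\top x_i$. Because AC provides no IPD,
$\alpha_1$ is estimated by the method of moments: after centering every
matched moment at its AC target (the mean for each covariate, plus the
second raw moment $\mu^2 + \sigma^2$ for variance-matched continuous
covariates), $\hat\alpha_1$ minimizes the convex objective
$\sum_i \exp(\alpha_1^\top z_i)$, pooled over both AB arms. Its gradient
is exactly the weighted balance condition, so at the solution every
matched moment is balanced *exactly* (the package verifies a weighted
balance gap below $10^{-8}$). $\alpha_0$ is never estimated: it cancels
from every weighted average, and weights are normalized to sum to $N$
only for reporting.

The entropy-balancing variant asks for the weight set closest to uniform
in the Kullback–Leibler sense subject to the same constraints. Its dual
is the log-partition function of the same exponential family, so the two
weight sets coincide; `fit_entropy_weights()` solves the dual by BFGS
with a Newton polish — a deliberately separate code path from the Newton
solver in `fit_maic_weights()` — and the package checks the two agree to
$10^{-6}$ on random instances. Any precision advantage of entropy
balancing must therefore come from the variance estimator, not the
weights; both methods share the uncertainty machinery here.

Numerical choices: moment columns are scaled to unit SD internally
(mixed-unit covariates otherwise produce badly conditioned Hessians) and
coefficients are reported back on the raw scale; Newton iterations use
step-halving with a BFGS fallback, and convergence is declared when the
weighted scaled-moment means fall below $10^{-10}$; collinear moment
columns are removed by rank-revealing QR with a warning naming them. A
target mean outside the observed support of a covariate can never be
balanced by positive weights, so it is a hard error, not a silent set of
extreme weights. Matching targets equal to the observed IPD means yields
$\alpha = 0$ and uniform weights, so with no effect-modifier imbalance
*no adjustment occurs* and MAIC reproduces the Bucher estimate exactly —
a property the test suite asserts to $10^{-12}$.

Diagnostics report the weight distribution, the largest weight shares,
and the effective sample size $\mathrm{ESS} = (\sum w)^2 / \sum w^2$,
pooled and per arm. The ESS treats the weights as fixed and tends to
understate the true effective information; it is a screening tool, not a
variance estimate.

## STC: simulated treatment comparison

The outcome regression fitted to the AB IPD is

$$g(\mu_t(x)) = \beta_0 + \beta_1^\top x +
  (\beta_B + \beta_2^\top x_{EM})\,\mathbb 1\{t = B\},$$

a GLM with Gaussian errors and identity link for continuous outcomes, or
Bernoulli errors with logit/log link for binary ones. All declared
covariates enter the prognostic term $\beta_1$; only declared effect
modifiers receive interactions $\beta_2$. The comparison must be formed
on the same scale as the model — mixing scales destroys additivity and
the meaning of effect modification, and is refused.

Absolute outcomes in the AC population can be predicted two ways:

* **Plug-in**: substitute the published covariate means. On the identity
  scale this is exact; on any nonlinear scale it is systematically
  biased, because $\mathbb E[g^{-1}(\eta(X))] \neq
  g^{-1}(\eta(\mathbb E[X]))$ — aggregation bias. The result carries a
  mandatory warning whenever the link is not the identity.
* **Simulation**: draw covariate vectors from a joint distribution
  reconstructed from the published marginals and average the
  back-transformed predictions. A Gaussian copula is used (the marginals
  published never identify a joint law; the copula is the conventional
  minimal completion), with correlations imputed from the AB IPD's
  Pearson correlations unless supplied. Binary covariates are generated
  by thresholding the latent normal at the published proportion.

The default draw count is $10^5$ (floor $10^4$); the Monte-Carlo error
of the average is printed separately rather than folded into the
reported SE, so users can verify it is negligible rather than have
simulation noise inflate the interval. Whether binary covariates should
preserve tetrachoric rather than Pearson correlations is not settled;
Pearson is used and documented.

## Anchored and unanchored comparisons

With predictions $\hat Y_A^{(AC)}, \hat Y_B^{(AC)}$ in hand,

$$\hat\Delta_{BC}(AC) =
\big(g(\bar Y_C^{(AC)}) - g(\bar Y_A^{(AC)})\big) -
\big(g(\hat Y_B^{(AC)}) - g(\hat Y_A^{(AC)})\big)
\quad\text{(anchored)},$$

$$\hat\Delta_{BC}(AC) = g(\bar Y_C^{(AC)}) - g(\hat Y_B^{(AC)})
\quad\text{(unanchored)}.$$

The anchored form preserves within-trial randomization and requires
conditional constancy of *relative* effects (no unobserved
effect-modifier imbalance). The unanchored form discards the anchor and
requires conditional constancy of *absolute* effects — every prognostic
variable and effect modifier accounted for — which is widely regarded as
infeasible; the package refuses an unanchored analysis whenever the
caller declares a connected network, and otherwise attaches a mandatory
warning that residual bias is unquantified.

Covariate-role hygiene follows the adjustment recommendations encoded in
`check_assumptions()`: anchored weighting should match all effect
modifiers and no purely prognostic variables (over-matching costs
precision without removing bias); anchored regression should include all
imbalanced effect modifiers; unanchored anything must include every
declared variable. Every result names its scale and target population.

## Transport and absolute effects

Population-adjusted estimates apply to the AC population, which is
rarely the decision target. Under the *shared effect modifier*
assumption for a treatment set $\mathcal T$ — same effect modifiers with
identical interaction coefficients for all treatments in $\mathcal T$ —
the between-treatment contrast is population-invariant,
$d_{tu}(P) = d_{tu}(Q)$ for $t,u \in \mathcal T$, and
`transport_effect()` relabels an estimate to any stated target
population (with a warning that the assumption needs clinical
justification; treatments in the same class are the plausible case).
Without it, transporting is an error. Given a baseline $\bar Y_A(P)$
(e.g. from a registry, with a user-supplied SE treated as independent),
absolute effects back-calculate as
$\hat Y_t(P) = g^{-1}(g(\bar Y_A(P)) + \hat\Delta_{At}(P))$.

## Uncertainty

The MAIC weights are estimated, and both arm averages share them. The
sandwich estimator stacks the estimating equations of the whole
procedure — $K$ moment-balance equations for $\alpha$ plus the two
weighted-mean equations — and computes the M-estimation variance
$A^{-1} B A^{-\top}/N$. The published description of MAIC cites a robust
sandwich without reproducing its algebra, so this stacked form is the
package's own construction; it is validated two independent ways: with
no matched moments it collapses to the classical robust SE of each arm
mean (asserted analytically in the tests), and at study sizes its SE
sits within 10% of both the bootstrap SE and the empirical SD of the
estimator over replications, with 95% CI coverage inside [0.93, 0.97].

Aggregate-trial variance enters at the comparison stage by the delta
method ($\mathrm{dg}(\bar Y)^2\,\mathrm{se}^2$ terms), treating AC
summaries as independent of the AB-derived predictions — different
trials. The unified bootstrap resamples patients within each AB arm,
re-runs the full pipeline per replicate, and resamples AC summaries
parametrically (binomial counts, or normal means); replicate seeds are
derived from the master seed by a counter, failed replicates are dropped
and counted, and more than 10% failures is an error. Binary arms with
zero or all events receive a 0.5 continuity correction before log/logit
transforms. 95% intervals are normal-theory on the linear predictor
scale, back-transformed endpoint-wise.

## The simulation engine and what it shows

`scenario_config()` defines a two-trial world generated from
$g(\mu) = \beta_0 + \beta_1^\top x + (d_{t}(0) +
\gamma_t^\top x_{EM})\mathbb 1\{\text{arm}=t\}$, with per-population
covariate means, and `run_study()` replicates it, reporting bias (with
its MC error), empirical and mean reported SE, coverage, mean ESS and
failures per method. The default scenario is a deliberately plain
imbalance: one standard-normal covariate, both prognostic
($\beta_1 = 1$) and an effect modifier for B only ($\gamma_B = 1$,
$\gamma_C = 0$), mean 0.2 in AB versus 0.6 in AC, continuous outcomes
with unit residual SD, 500 patients per arm — large enough that
$4\,\mathrm{SD}/\sqrt n$ checks are sharp, small enough that a
1000-replicate study runs in seconds. Under it the standard indirect
comparison is off by exactly $\gamma_B \times 0.4$ while anchored MAIC
and STC are unbiased; omitting an imbalanced prognostic covariate from
an *unanchored* analysis reintroduces bias of the size of the omitted
shift; and with $\gamma_B = \gamma_C$ the estimated contrast transports
unchanged to a distinct population.

Truths are analytic on the identity scale and computed by $10^6$-draw MC
integration otherwise (the marginal contrast on a nonlinear scale is not
a linear function of covariate means). The AC trial is simulated at
finite size by default so target noise is present as in practice;
`infinite_ac = TRUE` substitutes population summaries for sharp oracle
checks. "Unbiased" assertions in the tests use
$|\text{bias}| < \max(0.02,\ 2\times\text{MC error})$.

What passing these simulations does *not* show: the generator draws
covariates from the same family the STC model fits and the copula
assumes, so it cannot detect model misspecification, non-additive effect
modification, measurement error in covariates, or unobserved effect
modifiers — precisely the risks the assumption warnings exist to keep in
front of the analyst. Survival outcomes, multi-arm IPD trials, per-arm
covariate reporting, and arm-splitting weighting schemes are out of
scope throughout.

## A worked example

```{r example}
scenario <- scenario_config()       # the default imbalance scenario
gen <- generate_scenario(scenario, seed = 42)
res <- maic_analysis(gen$ab, gen$aggregate, scale = "identity")
res
weight_summary(attr(res, "weights"))
bucher_analysis(gen$ab, gen$aggregate, "identity")$estimate
true_effects(scenario, "AC")$d_bc
```
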