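# popadjust

Population-adjusted indirect treatment comparisons when individual
patient data (IPD) exist for one trial and only published aggregate data
for the other.

## The problem

Health-technology appraisals routinely need a comparison of two
treatments, B and C, that were never compared head to head: a
manufacturer has IPD for its own AB trial, while the competitor's AC
trial is available only as published summaries (per-arm sample sizes,
summary outcomes, covariate means/SDs/proportions). The standard
anchored indirect comparison on a linear predictor scale with link *g*,

    Δ̂_BC = Δ̂_AC(AC) − Δ̂_AB(AB),   Δ̂_AB(AB) = g(Ȳ_B) − g(Ȳ_A),

assumes every effect modifier is equally distributed in the two trial
populations. When conditional relative effects are
d_AB(x_EM) = d_AB(0) + γᵀx_EM and the effect-modifier means differ, that
comparison is biased by γ_Bᵀ(E[X_EM|AC] − E[X_EM|AB]).

`popadjust` implements the two population-adjustment families used in
this setting, their diagnostics, their variance estimators, and a
simulation engine that measures their bias and coverage:

* **MAIC** (matching-adjusted indirect comparison): weights each AB
  patient by the estimated odds of enrollment in AC, log-linear in the
  matched moments, estimated by the method of moments — minimizing the
  convex objective Σᵢ exp(α₁ᵀzᵢ) over moments centered at the aggregate
  targets, so every matched mean (and optionally variance) is balanced
  exactly. An entropy-balancing variant solves the dual program directly
  and coincides with the method-of-moments weights. Diagnostics include
  the effective sample size ESS = (Σw)²/Σw², weight quantiles and top
  shares, and a pre/post balance table.
* **STC** (simulated treatment comparison): fits
  g(μ_t(x)) = β₀ + β₁ᵀx + (β_B + β₂ᵀx_EM)·1{t=B} to the AB IPD and
  predicts absolute arm outcomes in the AC population, either by
  plugging in the published covariate means (exact on the identity
  scale, systematically biased otherwise — aggregation bias) or by
  averaging predictions over a Gaussian-copula draw from the published
  marginals with IPD-imputed correlations.
* **Anchored and unanchored estimators** (the unanchored form is
  refused while a connected network is declared), delta-method /
  sandwich / bootstrap standard errors, transport of contrasts to a
  stated target population under the shared effect modifier assumption,
  and back-calculation of absolute effects from a target baseline.
* A **simulation engine** (`scenario_config()`, `generate_scenario()`,
  `true_effects()`, `run_study()`) with analytic truths on the identity
  scale and Monte-Carlo truths otherwise.

## Worked example

The default scenario has one covariate that is both prognostic and an
effect modifier for B (γ_B = 1, γ_C = 0), mean 0.2 in AB vs 0.6 in AC,
500 patients per arm:

```r
library(popadjust)
scenario <- scenario_config()
gen <- generate_scenario(scenario, seed = 42)
maic_analysis(gen$ab, gen$aggregate, scale = "identity")
#> Anchored comparison: B vs C (identity scale), population: AC
#>   method: maic
#>   estimate: -1.2760 (se 0.1636), 95% CI [-1.5967, -0.9554]
#>   ESS: 835.6
#>   note: comparison carried out on the identity linear predictor scale
#>   note: target population: AC
#>   note: anchored comparison assumes conditional constancy of relative
#>         effects: all effect modifiers (on the identity scale) are
#>         accounted for
bucher_analysis(gen$ab, gen$aggregate, "identity")$estimate
#> [1] -0.781704
true_effects(scenario, "AC")$d_bc
#> [1] -1.1
```

The true B-vs-C effect in the AC population is −1.1. The standard
indirect comparison returns −0.78 — off by the unadjusted
effect-modifier shift γ_B × 0.4 — while the anchored MAIC estimate
(−1.28 ± 0.16) covers the truth. `weight_summary()` shows the price of
reweighting: the effective sample size drops to 835.6 of 1000 patients
(83.6%).

Real analyses are driven by one auditable YAML config
(`run_analysis("analysis.yaml", out_dir = "results")`), which writes
`results.json`, `balance.csv`, `weights.csv`, weight diagnostics, and a
plain-text assumptions statement; `inst/cli/popadjust.R` is a thin
command-line wrapper with subcommands `maic`, `maic_entropy`, `stc`,
`bucher`, and `simulate`.

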