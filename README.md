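# mnhcea

Bayesian cost-effectiveness and affordability analysis of maternal and
newborn health (MNH) interventions evaluated in cluster-randomised trials.

The package was built around a 2×2 factorial cluster-randomised trial in
rural Malawi that evaluated community mobilisation through women's groups
(CI), health-facility quality improvement (FI), and both combined (FICI),
against current practice. It is aimed at health economists and trial
statisticians who need to go from cluster-level mortality counts and an
intervention cost ledger to decision-ready quantities: deaths and DALYs
averted, ICERs, expected incremental benefit, acceptability curves, the
expected value of perfect information, and national scale-up/affordability
projections.

## What it computes

**Effects.** Cluster-level totals of births, combined stillbirths +
neonatal deaths ("baby mortality") and maternal deaths are modelled with
two Bayesian logistic regressions sharing a covariate design (district,
urban/rural stratum, intervention indicators):

- a *factorial* model with CI and FI main effects (two-arm CI vs no-CI and
  two-arm FI vs no-FI), and
- a *single-comparison* model for one-arm FICI vs one-arm control.

Priors are N(0, 10⁴) on the log-odds scale, with corresponding baby and
mother coefficients treated as a bivariate normal. Posterior draws come
from a built-in adaptive random-walk Metropolis-within-Gibbs sampler with
split-R̂ and effective-sample-size diagnostics. When only published
summaries are available, matched draws can be emulated from the odds-ratio
credible intervals instead (`emulate_posterior()`).

**Outcomes.** Each posterior odds ratio draw is converted to deaths
averted via the control-area rate, `p1 = OR·odds0/(1 + OR·odds0)`, then to
DALYs averted with life-expectancy weights (86.0 years per baby, 53.27 per
mother; localised variants 45.0/28.1), with no age weights or discounting.

**Decision analysis.** With fixed costs C₁ and effect draws E₁ against a
zero-cost, zero-effect current practice:

- ICER = (C₁−C₀)/(E₁−E₀) = C₁/E₁, with dominance flags,
- EIB(k) = k·E₁ − C₁ at willingness-to-pay k ($ per DALY averted),
- CEAC: the share of simulations in which an option has the higher net
  benefit,
- EVPI(k) = E[maxᵢ NBᵢ] − maxᵢ E[NBᵢ],
- an incremental frontier with strict and extended dominance pruning.

**Scale-up and affordability.** Annualised costs and effects are projected
over 5–20-year horizons with differential discounting (year one
undiscounted), scaled to the national population by the births ratio, and
expressed as a share of the national MNH budget.

## Worked example

The one-call pipeline reconstructs the full analysis from the packaged
published summaries (Monte Carlo emulation of the posteriors, baselines
calibrated to the published mean deaths averted):

```r
library(mnhcea)
res <- run_pipeline(n_draws = 50000, seed = 1)
summary(res$cea)
#>   option    cost mean_dalys_averted   icer   status      eib   ceac prob_best
#> 1     CI 5348790              67351  79.42 tradeoff 47184881 0.9782   0.74676
#> 2     FI 5592211              19859 281.60 tradeoff  9897661 0.6639   0.09676
#> 3   FICI 5470501              37547 145.70 tradeoff 23816362 0.9329   0.15586
```

Read: against current practice the community intervention costs $79.4 per
DALY averted, the facility intervention $282, and the combined intervention
$146 (one-arm basis). At the reference threshold of $780 per DALY (Malawi's
per-capita GDP) the expected incremental benefit of CI is about $47.2M and
its probability of being cost-effective is 98%; FI only reaches 66%. In the
three-way comparison at two-arm parity FI is strictly dominated:

```r
res$three_way$frontier
#>   label     cost   effect    status icer_vs_previous
#> 1    CI  5348790 67350.86  frontier          79.4168
#> 2    FI  5592211 19858.81 dominated               NA
#> 3  FICI 10941002 75094.52  frontier         722.1665
```

The affordability table (`res$affordability`) prices a nationwide scale-up
at $27.7M/yr for CI and $56.8M/yr for FICI — 6.8% and 13.8% of the
estimated $410M annual MNH expenditure — and `res$scenarios` sweeps the
27-scenario horizon × discounting grid, under which FICI is the optimal
choice at $780/DALY in the default scenario.

The same pipeline runs from cluster data: pass
`mode = "from_cluster_data"` with your records (or a synthetic trial from
`simulate_trial()`), and the Bayesian models are fitted instead of
emulated.

## Package layout

- `cost_summary()`, `build_cost_summary()`, `currency_table()` — the cost
  model (joint-cost allocation, straight-line capital annualisation,
  conversion to constant 2013 international dollars).
- `trial_design()`, `simulate_trial()` — synthetic factorial trials with
  known-truth odds ratios.
- `fit_mortality_model()`, `emulate_posterior()` — the effect models.
- `deaths_averted()`, `to_dalys()`, `convert_draws()` — outcome
  conversion.
- `cea()`, `icer()`, `eib()`, `ceac()`, `evpi()`, `ce_frontier()` — the
  decision analysis.
- `scale_up()`, `scenario_grid()`, `affordability_table()` — scale-up and
  affordability.
- `run_pipeline()` — the end-to-end driver.

See the methods vignette (`vignettes/cost-effectiveness-methods.Rmd`) for
the modelling assumptions, default parameter choices and limitations.
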