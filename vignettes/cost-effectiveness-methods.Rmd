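---
title: "Methods: Bayesian cost-effectiveness and affordability of MNH interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian cost-effectiveness and affordability of MNH interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnhcea)
```

# The decision problem

Two interventions against maternal and neonatal mortality — community
mobilisation through women's groups (CI) and health-facility quality
improvement (FI) — were evaluated together and separately in a 2×2
factorial cluster-randomised trial in rural Malawi. A policymaker choosing
among CI, FI, the combination (FICI) and current practice needs to know
what each option costs per DALY averted, how certain that judgement is,
and whether a national scale-up fits inside the maternal-and-neonatal
health (MNH) budget. This package implements that full chain as testable
components.

# The cost model

Costs are treated from the provider perspective as *fixed* (there is no
cluster-level cost variation to estimate from), structured as a one-off
start-up cost plus three annual streams: implementation, maintenance
(recurring recruitment/retraining) and external technical assistance.

Choices a user can revisit:

* **Joint-cost allocation** (`joint_rule()`): programme costs not
  attributable to a single intervention are split by fixed proportions,
  default 50/50, reflecting equal office space and shared administration;
  the unallocated remainder is excluded from intervention costs and
  conservation (shares + remainder = total) is enforced exactly.
* **Capital annualisation** (`annualize_capital()`): straight-line
  depreciation over the stated lifespan, no interest.
* **Currency** (`currency_table()`): amounts are deflated to 2013 local
  prices with a per-year CPI multiplier and converted at 105.8 Malawi
  Kwacha per 2013 international dollar; GBP/USD ledger lines need
  year-specific exchange rates supplied by the user. All arithmetic is at
  full floating precision; rounding to whole dollars happens only in
  reports, which is why rebuilt totals can differ from published ones by a
  unit or two.
* **Ledger aggregation** (`build_cost_summary()`): annual categories are
  averaged over the calendar years present in the ledger; start-up lines
  are summed as a one-off block without annualisation (in a trial costing
  the full purchase belongs to start-up); allocated joint lines are folded
  into implementation. Scenario and currency configuration are ordinary
  function arguments rather than a configuration-file format — in an R
  package the call is the configuration, and it keeps the surface
  scriptable.

The packaged `trial_costs()` fixture carries the published per-component
values in 2013 international dollars, because the underlying NGO ledger is
not public; `inst/extdata/synthetic_ledger_ci.csv` is a *synthetic*
demonstration ledger whose start-up block reproduces the published CI
start-up total, not a reconstruction of real accounts.

# The effect model

Deaths are modelled at the cluster level: for cluster $i$ with $n_i$
births,

$$d_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
  \mathrm{logit}(p_i) = \beta_0 + \beta_{\mathrm{district}(i)}
  + \beta_{\mathrm{urban}} u_i + \beta_{CI}\,CI_i + \beta_{FI}\,FI_i,$$

fitted separately but jointly sampled for the two outcomes: combined
stillbirth + neonatal deaths ("baby") and maternal deaths ("mother"),
both per birth (one mother per birth — the trial counted equal populations
of mothers and babies). The factorial model codes CI as 1 in the CI and
FICI arms and FI as 1 in the FI and FICI arms, with **no interaction
term**; the combined effect is estimated by a separate FICI-vs-control
fit. That mirrors the two comparisons the factorial design supports and
keeps each reported odds ratio interpretable on its own.

Priors are $N(0, 10^4)$ per coefficient on the log-odds scale —
effectively flat over any plausible odds ratio. Corresponding baby and
mother coefficients are treated as a bivariate normal; the prior
cross-outcome correlation is not identified by any published information,
so it is set to zero, which factorises the posterior and is the
least-informative choice. The model is fixed-effects only: with ~15
clusters per arm and aggregated counts there is little information to
separate a cluster random effect from binomial noise, and the
synthetic-data generator provides overdispersion to stress-test the
consequences of that reading.

## Sampling and numerics

The sampler is a self-contained adaptive random-walk
Metropolis-within-Gibbs: one Gibbs block per outcome equation, each with a
multivariate normal proposal. The proposal is initialised at the
maximum-likelihood estimate with its inverse-information covariance when
the GLM exists (zeros and an identity proposal otherwise, e.g. all-zero
data), the global scale follows a Robbins–Monro recursion toward 23.4%
acceptance, and the proposal shape is re-estimated from the accumulating
burn-in history every 500 iterations. Adaptation stops at the end of
burn-in, so retained draws come from a fixed Markov kernel. The binomial
log-likelihood is evaluated through `plogis(eta, log.p = TRUE)`, which is
stable at extreme linear predictors.

Convergence is reported, not enforced: split-chain potential scale
reduction above 1.05 on any monitored coefficient raises a warning with
the offending parameter attached, and effective sample sizes use Geyer's
initial-positive-sequence truncation. Degenerate inputs are defined
behaviour — zero births contribute nothing to the likelihood (the
posterior reproduces the prior), and all-zero deaths yield wide posteriors
rather than errors.

The default schedule (2 chains × 510,000 iterations, 10,000 burn-in,
thinning 10 → 100,000 saved draws) matches the original trial analysis.
The test suite uses shorter schedules sized to each check: the dense-grid
oracle comparison (total variation < 0.02 on a two-cluster problem) uses
2 × 101,000 iterations thinned by 5, known-truth recovery uses 2 × 7,000,
and the 50-seed null-trial coverage check uses 2 × 2,500 on 12-cluster
trials — enough draws that Monte-Carlo error is small relative to each
test's tolerance.

## Emulated posteriors

When only published summaries are available, `emulate_or_draws()`
reconstructs draws from a lognormal whose 2.5th/97.5th quantiles match the
published credible interval. Two caveats are inherent: the implied mean
odds ratio is $\exp(\mu + \sigma^2/2)$ and may differ slightly from the
published posterior mean, and baby/mother (and cross-intervention) draws
are emulated independently because the joint posterior correlation is not
recoverable from interval summaries. Quantities that depend on those
correlations — notably probabilities in head-to-head comparisons of
options fitted in one joint model — are therefore only approximated by
emulation; directions are stable, magnitudes can shift by a few points.

# Outcome conversion

The control-area death probability $p_0$ maps an odds-ratio draw to an
intervention-area probability
$p_1 = \mathrm{OR}\,\omega_0/(1+\mathrm{OR}\,\omega_0)$ with
$\omega_0 = p_0/(1-p_0)$, and deaths averted are $n\,(p_0 - p_1)$ over the
comparison population ($n$ = 54,000 births per arm × 2 arms for CI/FI, ×1
for FICI; FICI outcomes and costs are doubled *explicitly* when compared
with the two-arm options). DALY weights are 86.0 years per baby death and
53.27 per maternal death (localised variants 45.0/28.1), no age weights,
no discounting within the trial window.

The published tables do not state $p_0$, so the summary-driven pipeline
*calibrates* it by root-finding (`calibrate_p0()`) until the mean deaths
averted match the published means. That reconstruction reproduces the
published DALY scale but is not observed data, and it is labelled as such
wherever it is used.

# Decision analysis

All decision quantities are computed on matched draws with costs entering
as degenerate distributions (per-draw costs are accepted for reuse).
Tie-breaking is strict everywhere: a tie in net benefit counts as "not
more cost-effective", and a draw with two options at the joint maximum
counts toward neither's probability of being best, so reported
probabilities are conservative. EVPI is population-level. The incremental
frontier sorts by mean cost, removes strictly dominated options (against
the origin too), collapses exact duplicates to one point, and removes
extended dominance by requiring non-decreasing ICERs along the frontier.
An ICER with zero incremental effect is returned as `NA` with a classed
warning carrying the incremental cost, rather than an error — degenerate
comparisons occur naturally in grids and fuzz tests.

The default threshold grid runs $0$–$2{,}500$ in steps of 10 and always
contains the reference value 780 \$/DALY, Malawi's 2013 per-capita GDP.

# Scale-up and affordability

Annual cost is recurring + external cost per year; effects are annualised
by dividing trial-period draws by 2.25 years (same effect assumed each
year). Projections use a **year-one-undiscounted** convention: year 1
accrues in full (including the entire start-up block) and years
$2..H$ are discounted by $(1+r)^{-(t-1)}$. Many texts discount from year
one; this convention is stated explicitly because the choice changes
totals by a factor $(1+r)$. Effects use the same indexing, by symmetry;
maintenance is discounted identically to implementation. Defaults: 10-year
horizon, 3% on costs, 2% on effects; the sensitivity grid crosses horizons
5/10/20 with cost rates 0/3/10% and effect rates 0/2/3% (27 scenarios,
each self-contained).

National scaling multiplies annual costs by the ratio of national to trial
mothers-and-babies — both constructed as births × 2, so the ratio equals
the births ratio (≈12.51 for 2010 Malawi: population 15,013,694 × crude
birth rate 0.04). Affordability divides the nationwide annual cost by the
MNH budget (per-capita health expenditure $228.7 × population × 11.95%
MNH share, 2010 values; any `malawi_context()` can be substituted).

# The synthetic-data generator

`simulate_trial()` emulates the study conditions: four arms (control, CI,
FI, FICI), 15 clusters per arm, 54,000 births per arm over 2.25 years
split near-equally across clusters with multinomial jitter, three
districts and an urban/rural stratum with small fixed log-odds offsets
(±0.05; ~10% urban), control-arm probabilities of 0.05 for baby death and
0.007 for maternal death (consistent with rural Malawi around 2010), true
odds ratios defaulting to the published posterior means, and an optional
normal cluster-level log-odds perturbation (sd 0.1) to induce
overdispersion the fixed-effects model does not capture. The real trial's
exact cluster count and per-cluster birth distribution are in its data
deposit, not the published text, so these defaults are documented
stand-ins.

What passing tests on generated data do show: the sampler recovers known
log odds ratios within Monte-Carlo tolerance at large birth counts, and
null trials are covered at roughly the nominal 95% rate. What they do not
show: robustness to real-data features the generator omits — time-varying
rates, migration between clusters, individual-level covariates, and
cost–effect correlation at cluster level (which the trial design itself
could not measure).

# Known limitations

* The FICI-vs-CI comparison from emulated summaries ignores the posterior
  correlation a joint three-way model would carry; its incremental ICER
  from published means (≈\$715/DALY) is therefore not comparable to a
  joint-model estimate, and head-to-head probabilities are approximate.
* Costs of health-worker time, morbidity effects and care-seeking changes
  are outside the costing perspective, as in the source trial.
* Published integer means carry half-unit rounding; arithmetic rebuilt
  from them (e.g. DALY totals from rounded deaths averted) can differ from
  published values by up to ~0.3% for small-magnitude rows.
* The affordability model assumes costs and effects scale proportionally
  with population, with no economies of scale.
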