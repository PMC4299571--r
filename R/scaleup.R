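#' Scale-up scenario configuration
#'
#' A deterministic multi-year projection of the trial's annualised costs and
#' effects: a time horizon, separate annual discount rates for costs and
#' effects (differential discounting, defaults 3% and 2%), the ratio of the
#' national to the trial population of mothers and babies, and the
#' willingness-to-pay threshold at which options are compared.
#'
#' @param horizon_years Time horizon (years; default 10).
#' @param cost_discount Annual discount rate on costs (default 0.03).
#' @param effect_discount Annual discount rate on effects (default 0.02).
#' @param population_ratio National-to-trial population ratio; the default
#'   is computed from [malawi_context()] via [population_ratio()].
#' @param threshold_k Willingness-to-pay ($ per DALY averted).
#' @return An object of class `scaleup_scenario`.
#' @export
scaleup_scenario <- function(horizon_years = 10,
                             cost_discount = 0.03,
                             effect_discount = 0.02,
                             population_ratio = NULL,
                             threshold_k = 780) {
  if (is.null(population_ratio)) {
    population_ratio <- population_ratio(malawi_context())
  }
  stopifnot(horizon_years >= 1,
            cost_discount >= 0, cost_discount < 1,
            effect_discount >= 0, effect_discount < 1,
            population_ratio > 0, threshold_k >= 0)
  structure(list(horizon_years = as.integer(horizon_years),
                 cost_discount = cost_discount,
                 effect_discount = effect_discount,
                 population_ratio = population_ratio,
                 threshold_k = threshold_k),
            class = "scaleup_scenario")
}

#' National-to-trial population ratio
#'
#' Both numerator and denominator count mothers and babies (twice the
#' births), so the ratio equals the births ratio; both constructions are
#' available.
#'
#' @param ctx A [malawi_context()].
#' @param count `"mothers_and_babies"` (default) or `"births"`.
#' @return The scaling ratio (about 12.51 for Malawi 2010).
#' @export
#' @examples
#' population_ratio(malawi_context())
population_ratio <- function(ctx = malawi_context(),
                             count = c("mothers_and_babies", "births")) {
  stopifnot(inherits(ctx, "national_context"))
  count <- match.arg(count)
  mult <- if (count == "mothers_and_babies") 2 else 1
  (ctx$population * ctx$crude_birth_rate * mult) /
    (ctx$trial_population * ctx$crude_birth_rate * mult)
}

#' Annualise trial-period quantities
#'
#' Costs in the trial summary are already per-year (implementation costs
#' were divided by the 2.25-year trial period when the summary was built;
#' maintenance and external costs are annual by nature), so the annual cost
#' is simply their sum. Effects measured over the trial period are divided
#' by its length, assuming the same effect per year. Start-up costs are kept
#' separate: they enter year one of any projection in full.
#'
#' @param summary A [cost_summary()].
#' @param outcomes An `outcome_draws` data.frame (see [convert_draws()]).
#' @param trial_years Trial period length (default 2.25).
#' @return A list: `annual_cost` ($/yr), `start_up` ($),
#'   `annual_effect_draws` (DALYs averted per year, one per draw).
#' @export
annualize_trial_quantities <- function(summary, outcomes,
                                       trial_years = 2.25) {
  stopifnot(inherits(summary, "cost_summary"), trial_years > 0,
            inherits(outcomes, "outcome_draws"))
  list(annual_cost = annual_cost(summary),
       start_up = summary$start_up,
       annual_effect_draws = outcomes$dalys_averted / trial_years)
}

#' Present value of an annual stream
#'
#' Year one is undiscounted; years 2..horizon are discounted by
#' `(1+rate)^-(t-1)`. At rate zero this reduces exactly to
#' `annual * horizon`.
#'
#' @param annual Amount accruing each year.
#' @param rate Annual discount rate.
#' @param horizon Number of years (>= 1).
#' @return Discounted total; vectorised over `annual`.
#' @export
#' @examples
#' discounted_stream(100, 0.03, 10) # 878.61
discounted_stream <- function(annual, rate, horizon) {
  stopifnot(horizon >= 1, rate >= 0, rate < 1)
  horizon <- as.integer(horizon)
  f <- if (horizon == 1) 1 else 1 + sum((1 + rate)^-(seq_len(horizon - 1)))
  annual * f
}

#' Nationwide annual cost
#'
#' @param annual_cost Trial annual cost ($/yr).
#' @param ratio National-to-trial population ratio.
#' @return Nationwide cost ($/yr).
#' @export
national_annual_cost <- function(annual_cost, ratio) {
  stopifnot(ratio > 0)
  annual_cost * ratio
}

#' Annual national expenditure on maternal and neonatal health
#'
#' @param ctx A [malawi_context()].
#' @return Per-capita health expenditure x population x MNH share ($/yr).
#' @export
mnh_budget <- function(ctx = malawi_context()) {
  stopifnot(inherits(ctx, "national_context"))
  ctx$per_capita_health_exp * ctx$population * ctx$mnh_share
}

#' Share of the MNH budget a nationwide scale-up would absorb
#'
#' @param national_cost Nationwide annual cost ($/yr).
#' @param budget Annual MNH budget ($/yr); must be positive.
#' @return Proportion (report as a percentage to one decimal).
#' @export
budget_share <- function(national_cost, budget = mnh_budget()) {
  if (!is.finite(budget) || budget <= 0) {
    stop("'budget' must be positive", call. = FALSE)
  }
  national_cost / budget
}

#' Scale-up and affordability table
#'
#' Reproduces the trial's affordability summary: per-year trial and
#' nationwide populations and costs, cost per person (mother or baby,
#' counted separately), the MNH budget, and each intervention's budget
#' share. The combined intervention's costs are doubled to two-arm parity
#' before scaling so the trial-to-nation ratio stays valid.
#'
#' @param costs Named list of [cost_summary()] objects; one-arm summaries
#'   are rescaled to two arms.
#' @param ctx A [malawi_context()].
#' @return A `data.frame`, one row per intervention.
#' @export
#' @examples
#' affordability_table(trial_costs()[c("CI", "FI", "FICI")])
affordability_table <- function(costs, ctx = malawi_context()) {
  stopifnot(inherits(ctx, "national_context"))
  ratio <- population_ratio(ctx)
  trial_pop <- ctx$trial_population * ctx$crude_birth_rate * 2
  national_pop <- ctx$population * ctx$crude_birth_rate * 2
  budget <- mnh_budget(ctx)
  rows <- lapply(costs, function(s) {
    s2 <- if (s$arms_covered == 1L) rescale_arms(s, 2L) else s
    ann <- annual_cost(s2)
    nat <- national_annual_cost(ann, ratio)
    data.frame(intervention = s$intervention,
               trial_annual_cost = ann,
               national_annual_cost = nat,
               cost_per_person = ann / trial_pop,
               budget_share = budget_share(nat, budget),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trial_population") <- trial_pop
  attr(out, "national_population") <- national_pop
  attr(out, "mnh_budget") <- budget
  attr(out, "ratio") <- ratio
  out
}

#' Evaluate one scale-up scenario
#'
#' Projects each option's annualised national costs and per-draw annual
#' effects over the scenario horizon with differential discounting (start-up
#' enters year one in full), then runs the probabilistic decision analysis
#' at the scenario threshold.
#'
#' @param costs Named list of [cost_summary()] objects (two-arm parity
#'   enforced as in [affordability_table()]).
#' @param outcome_list Named list of `outcome_draws` matching `costs`
#'   (already at two-arm parity; use [double_outcomes()] for FICI).
#' @param scenario A [scaleup_scenario()].
#' @param trial_years Trial period length used to annualise effects.
#' @return A list: `scenario`, `inputs` (the discounted [cea_input()]s),
#'   `cea` (the [cea()] at the scenario threshold), `best_option`,
#'   `prob_best`, `frontier`.
#' @export
scale_up <- function(costs, outcome_list, scenario = scaleup_scenario(),
                     trial_years = 2.25) {
  stopifnot(inherits(scenario, "scaleup_scenario"),
            identical(names(costs), names(outcome_list)))
  inputs <- lapply(names(costs), function(nm) {
    s <- costs[[nm]]
    s2 <- if (s$arms_covered == 1L) rescale_arms(s, 2L) else s
    ann <- annualize_trial_quantities(s2, outcome_list[[nm]], trial_years)
    total_cost <- scenario$population_ratio *
      (ann$start_up + discounted_stream(ann$annual_cost,
                                        scenario$cost_discount,
                                        scenario$horizon_years))
    eff <- scenario$population_ratio *
      discounted_stream(ann$annual_effect_draws,
                        scenario$effect_discount,
                        scenario$horizon_years)
    cea_input(nm, total_cost, eff)
  })
  names(inputs) <- names(costs)
  res <- cea(inputs, k = unique(sort(c(0, scenario$threshold_k))),
             kref = scenario$threshold_k)
  at_k <- res$by_k[res$by_k$k == scenario$threshold_k, ]
  best <- at_k$option[which.max(at_k$prob_best)]
  list(scenario = scenario,
       inputs = inputs,
       cea = res,
       best_option = best,
       prob_best = max(at_k$prob_best),
       frontier = res$frontier)
}

#' Sensitivity grid over horizons and discount rates
#'
#' Evaluates [scale_up()] over the cross of time horizons and cost/effect
#' discount rates (defaults give the 27-scenario grid: horizons 5/10/20,
#' cost rates 0/3/10%, effect rates 0/2/3%). Each scenario is evaluated
#' independently.
#'
#' @inheritParams scale_up
#' @param horizons,cost_rates,effect_rates Scenario axes.
#' @param population_ratio,threshold_k Passed to every scenario.
#' @return A `data.frame`, one row per scenario per option: discounted
#'   national cost, mean discounted DALYs averted, EIB at the threshold,
#'   probability best, best option of the scenario, and the option's
#'   frontier status and ICER.
#' @export
scenario_grid <- function(costs, outcome_list,
                          horizons = c(5, 10, 20),
                          cost_rates = c(0, 0.03, 0.10),
                          effect_rates = c(0, 0.02, 0.03),
                          population_ratio = NULL,
                          threshold_k = 780,
                          trial_years = 2.25) {
  if (is.null(population_ratio)) {
    population_ratio <- population_ratio(malawi_context())
  }
  grid <- expand.grid(horizon = horizons, cost_rate = cost_rates,
                      effect_rate = effect_rates)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- scaleup_scenario(grid$horizon[i], grid$cost_rate[i],
                           grid$effect_rate[i], population_ratio,
                           threshold_k)
    r <- scale_up(costs, outcome_list, sc, trial_years)
    at_k <- r$cea$by_k[r$cea$by_k$k == threshold_k, ]
    data.frame(horizon = grid$horizon[i],
               cost_rate = grid$cost_rate[i],
               effect_rate = grid$effect_rate[i],
               option = at_k$option,
               cost = vapply(r$inputs, mean_cost, numeric(1)),
               mean_dalys = vapply(r$inputs, mean_effect, numeric(1)),
               eib = at_k$eib,
               prob_best = at_k$prob_best,
               best_option = r$best_option,
               frontier_status =
                 r$frontier$status[match(at_k$option, r$frontier$label)],
               frontier_icer =
                 r$frontier$icer_vs_previous[match(at_k$option,
                                                   r$frontier$label)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
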