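test_that("discounted streams follow the year-one-undiscounted convention", {
  expect_equal(discounted_stream(100, 0, 10), 1000)
  expect_equal(discounted_stream(100, 0.5, 1), 100)
  # geometric-series oracle: 100 * (1 + (1 - 1.03^-9) / 0.03)
  expect_equal(discounted_stream(100, 0.03, 10),
               100 * (1 + (1 - 1.03^-9) / 0.03))
  expect_equal(discounted_stream(100, 0.03, 10), 878.6109,
               tolerance = 1e-4)
  # strictly decreasing in rate (horizon >= 2), increasing in horizon
  rates <- c(0, 0.02, 0.05, 0.1)
  expect_true(all(diff(sapply(rates, discounted_stream,
                              annual = 50, horizon = 8)) < 0))
  expect_true(all(diff(sapply(2:12, discounted_stream,
                              annual = 50, rate = 0.03)) > 0))
})

test_that("national scaling and budget shares reproduce the published table", {
  ctx <- malawi_context()
  ratio <- population_ratio(ctx)
  expect_equal(ratio, 12.5114, tolerance = 1e-4)
  expect_equal(population_ratio(ctx, "births"), ratio)

  pc <- published_costs()
  nat_ci <- national_annual_cost(annual_cost(trial_costs()$CI), ratio)
  nat_fi <- national_annual_cost(annual_cost(trial_costs()$FI), ratio)
  nat_fici <- national_annual_cost(
    annual_cost(rescale_arms(trial_costs()$FICI, 2L)), ratio)
  expect_equal(nat_ci, 27729225, tolerance = 1e-5)
  expect_equal(nat_fi, 29078474, tolerance = 1e-5)
  expect_equal(nat_fici, 56807699, tolerance = 1e-5)
  expect_equal(national_annual_cost(42, 1), 42)

  budget <- mnh_budget(ctx)
  # printed inputs are pre-rounded: the product agrees to ~1e-4
  expect_equal(budget, 410354347, tolerance = 1e-4)
  expect_equal(mnh_budget(malawi_context(population = 2 * ctx$population)),
               2 * budget)

  expect_equal(round(100 * budget_share(nat_ci, budget), 1), 6.8)
  expect_equal(round(100 * budget_share(nat_fi, budget), 1), 7.1)
  expect_equal(round(100 * budget_share(nat_fici, budget), 1), 13.8)
  expect_equal(budget_share(0, budget), 0)
  expect_error(budget_share(1, 0), "positive")
})

test_that("the affordability table matches the published per-person costs", {
  at <- affordability_table(trial_costs()[c("CI", "FI", "FICI")])
  expect_equal(attr(at, "trial_population"), 96000)
  expect_equal(round(attr(at, "national_population")), 1201096)
  expect_equal(round(at$cost_per_person, 2), c(23.09, 24.21, 47.30))
  expect_equal(round(100 * at$budget_share, 1), c(6.8, 7.1, 13.8))
})

test_that("a degenerate scenario reduces to single-year deterministic CEA", {
  cs <- cost_summary("X", 1000, 200, 50, 30)
  od <- convert_draws(cbind(baby_log_or = rep(log(0.9), 4),
                            mother_log_or = rep(0, 4)),
                      baseline_rates(0.05, 0.007, 54000, 2))
  sc <- scaleup_scenario(horizon_years = 1, cost_discount = 0,
                         effect_discount = 0, population_ratio = 1,
                         threshold_k = 780)
  r <- scale_up(list(X = cs), list(X = od), sc, trial_years = 2.25)
  expect_equal(r$inputs$X$cost, 1000 + 280)
  expect_equal(mean(r$inputs$X$effect), od$dalys_averted[1] / 2.25)
  expect_equal(r$cea$by_k$eib[r$cea$by_k$k == 780],
               780 * od$dalys_averted[1] / 2.25 - 1280)
})

test_that("annualisation divides effects, not already-annual costs", {
  cs <- trial_costs()$CI
  od <- convert_draws(cbind(baby_log_or = rnorm(10, -0.1, 0.01),
                            mother_log_or = rnorm(10, 0, 0.01)),
                      baseline_rates(0.05, 0.007))
  ann <- annualize_trial_quantities(cs, od)
  expect_equal(ann$annual_cost, annual_cost(cs))
  expect_equal(ann$start_up, cs$start_up)
  expect_equal(ann$annual_effect_draws, od$dalys_averted / 2.25)
})

test_that("the scenario grid covers 27 scenarios and responds to discounting", {
  eff <- trial_effects()
  outcome_of <- function(iv, seed) {
    row <- eff[eff$intervention == iv, ]
    pd <- emulate_posterior(row, 2000, seed = seed)
    p_b <- calibrate_p0(pd[, "baby_log_or"], row$babies_saved,
                        row$population)
    p_m <- calibrate_p0(pd[, "mother_log_or"], row$mothers_saved,
                        row$population)
    convert_draws(pd, baseline_rates(p_b, p_m, 54000,
                                     row$population / 54000))
  }
  outs <- list(CI = outcome_of("CI", 1), FI = outcome_of("FI", 2),
               FICI = double_outcomes(outcome_of("FICI", 3)))
  costs <- trial_costs()[c("CI", "FI", "FICI2")]
  names(costs) <- names(outs)
  grid <- scenario_grid(costs, outs)
  expect_equal(nrow(grid), 27 * 3)
  expect_equal(nrow(unique(grid[c("horizon", "cost_rate",
                                  "effect_rate")])), 27)

  # at the reference threshold the combined intervention leads under the
  # default scenario (10 years, 3% cost / 2% effect discounting)
  def <- grid[grid$horizon == 10 & grid$cost_rate == 0.03 &
                grid$effect_rate == 0.02, ]
  expect_true(all(def$best_option == "FICI"))
  expect_true(all(grid$frontier_status[grid$option == "FI"] == "dominated"))

  # heavier cost discounting (fixed effect discounting) raises every EIB
  for (er in c(0, 0.02, 0.03)) {
    sub <- grid[grid$effect_rate == er & grid$horizon == 10, ]
    for (opt in unique(sub$option)) {
      e <- sub$eib[sub$option == opt][order(sub$cost_rate[sub$option ==
                                                            opt])]
      expect_true(all(diff(e) >= 0))
    }
  }

  # each scenario is reproducible in isolation
  sc <- scaleup_scenario(10, 0.03, 0.02, threshold_k = 780)
  solo <- scale_up(costs, outs, sc)
  sub <- grid[grid$horizon == 10 & grid$cost_rate == 0.03 &
                grid$effect_rate == 0.02, ]
  at_k <- solo$cea$by_k[solo$cea$by_k$k == 780, ]
  expect_equal(sub$eib, at_k$eib)
  expect_equal(sub$prob_best, at_k$prob_best)
})
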