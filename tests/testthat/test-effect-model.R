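test_that("MCMC configuration arithmetic matches the saved draw count", {
  expect_equal(mcmc_config()$n_saved, 100000L)
  cfg <- mcmc_config(chains = 2, iterations = 5000, burnin = 1000,
                     thin = 4)
  expect_equal(cfg$n_saved, 2000L)
  expect_error(mcmc_config(iterations = 5001, burnin = 1000, thin = 4),
               "multiple")
  expect_error(mcmc_config(iterations = 500, burnin = 1000), "iterations")
})

test_that("fits are seed-reproducible and sized by the config", {
  tr <- simulate_trial(trial_design(n_clusters_per_arm = 5,
                                    births_per_arm = 10000), seed = 3)
  cfg <- test_mcmc(iterations = 1600, burnin = 600)
  f1 <- fit_mortality_model(tr, "factorial", mcmc = cfg, seed = 7)
  f2 <- fit_mortality_model(tr, "factorial", mcmc = cfg, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws$baby), cfg$n_saved)
  pd <- posterior_draws(f1, "CI")
  expect_equal(colnames(pd), c("baby_log_or", "mother_log_or"))
  expect_equal(nrow(pd), cfg$n_saved)
  expect_error(posterior_draws(f1, "FICI"), "one of")
})

test_that("the factorial fit recovers known truth on a large trial", {
  des <- trial_design(n_clusters_per_arm = 15, births_per_arm = 1e6,
                      or_baby = c(CI = 0.873, FI = 0.954,
                                  FICI = 0.873 * 0.954),
                      or_mother = c(CI = 0.957, FI = 1.228,
                                    FICI = 0.957 * 1.228),
                      cluster_sd = 0)
  tr <- simulate_trial(des, seed = 21)
  fit <- fit_mortality_model(tr, "factorial",
                             mcmc = test_mcmc(iterations = 7000,
                                              burnin = 2000), seed = 22)
  for (trt in c("CI", "FI")) {
    pd <- posterior_draws(fit, trt)
    for (oc in c("baby", "mother")) {
      x <- pd[, paste0(oc, "_log_or")]
      truth <- log(if (oc == "baby") des$or_baby[[trt]]
                   else des$or_mother[[trt]])
      expect_lt(abs(mean(x) - truth), 3 * sd(x))
    }
  }
})

test_that("the single-comparison fit recovers truth and relabelling inverts the OR", {
  des <- trial_design(n_clusters_per_arm = 10, births_per_arm = 5e5,
                      or_baby = c(CI = 1, FI = 1, FICI = 0.841),
                      or_mother = c(CI = 1, FI = 1, FICI = 1.287),
                      cluster_sd = 0)
  tr <- simulate_trial(des, seed = 31)
  tr <- tr[tr$arm %in% c("control", "FICI"), ]
  fit <- fit_mortality_model(tr, "single",
                             mcmc = test_mcmc(iterations = 7000,
                                              burnin = 2000), seed = 32)
  pd <- posterior_draws(fit, "FICI")
  expect_lt(abs(mean(pd[, "baby_log_or"]) - log(0.841)),
            3 * sd(pd[, "baby_log_or"]))

  # swapping the arm labels flips the sign of the log odds ratio
  swapped <- tr
  swapped$arm <- ifelse(tr$arm == "FICI", "control", "FICI")
  fit_sw <- fit_mortality_model(swapped, "single",
                                mcmc = test_mcmc(iterations = 7000,
                                                 burnin = 2000), seed = 32)
  pd_sw <- posterior_draws(fit_sw, "FICI")
  # the swapped posterior is the reciprocal: compare means and spread at a
  # Monte-Carlo tolerance from the effective sample sizes of both runs
  ess <- min(fit$diagnostics$ess[fit$diagnostics$parameter == "FICI"],
             fit_sw$diagnostics$ess[fit_sw$diagnostics$parameter == "FICI"])
  s <- sd(pd[, "baby_log_or"])
  expect_lt(abs(mean(pd[, "baby_log_or"]) + mean(pd_sw[, "baby_log_or"])),
            6 * s / sqrt(ess))
  expect_equal(sd(pd_sw[, "baby_log_or"]), s, tolerance = 0.15)

  expect_error(
    fit_mortality_model(tr[tr$arm == "control", ], "single"),
    "FICI and control")
  no_fi <- hand_clusters()
  no_fi <- no_fi[no_fi$arm %in% c("control", "CI"), ]
  expect_error(fit_mortality_model(no_fi, "factorial"), "variation")
})

test_that("two identical arms give an OR posterior centred at one", {
  rec <- data.frame(cluster_id = c("a", "b"), district = "D",
                    stratum = "rural", arm = c("control", "FICI"),
                    births = c(5000, 5000), baby_deaths = c(250, 250),
                    mother_deaths = c(35, 35), stringsAsFactors = FALSE)
  fit <- fit_mortality_model(rec, "single",
                             mcmc = test_mcmc(iterations = 11000,
                                              burnin = 1000), seed = 5)
  x <- posterior_draws(fit, "FICI")[, "baby_log_or"]
  expect_lt(abs(mean(x)), 2.5 * sd(x) / sqrt(200))  # generous ESS margin
})

test_that("the marginal posterior matches a dense grid oracle", {
  rec <- data.frame(cluster_id = c("a", "b"), district = "D",
                    stratum = "rural", arm = c("control", "FICI"),
                    births = c(1000, 1000), baby_deaths = c(50, 40),
                    mother_deaths = c(7, 6), stringsAsFactors = FALSE)
  # exact joint posterior of (intercept, log OR) on a dense grid,
  # marginalised over the intercept
  b0 <- seq(-3.6, -2.3, length.out = 300)
  b1 <- seq(-1.2, 0.8, length.out = 400)
  lp <- outer(b0, b1, function(x, y)
    50 * plogis(x, log.p = TRUE) + 950 * plogis(-x, log.p = TRUE) +
      40 * plogis(x + y, log.p = TRUE) +
      960 * plogis(-(x + y), log.p = TRUE) +
      dnorm(x, 0, 100, log = TRUE) + dnorm(y, 0, 100, log = TRUE))
  w <- exp(lp - max(lp))
  marg <- colSums(w)
  marg <- marg / sum(marg)
  breaks <- seq(-1.2, 0.8, length.out = 21)
  grid_p <- as.numeric(tapply(marg, cut(b1, breaks, include.lowest = TRUE),
                              sum))

  fit <- fit_mortality_model(rec, "single",
                             mcmc = mcmc_config(chains = 2,
                                                iterations = 101000,
                                                burnin = 1000, thin = 5),
                             seed = 9)
  d <- posterior_draws(fit, "FICI")[, "baby_log_or"]
  mc_p <- as.numeric(table(cut(pmin(pmax(d, -1.2), 0.8), breaks,
                               include.lowest = TRUE)) / length(d))
  expect_lt(0.5 * sum(abs(grid_p - mc_p)), 0.02)
})

test_that("with no data the posterior reproduces the prior", {
  rec <- data.frame(cluster_id = c("a", "b"), district = "D",
                    stratum = "rural", arm = c("control", "FICI"),
                    births = c(0, 0), baby_deaths = c(0, 0),
                    mother_deaths = c(0, 0), stringsAsFactors = FALSE)
  fit <- fit_mortality_model(rec, "single",
                             mcmc = mcmc_config(chains = 2,
                                                iterations = 12000,
                                                burnin = 4000, thin = 1),
                             seed = 2)
  pd <- posterior_draws(fit, "FICI")
  expect_lt(max(abs(colMeans(pd))), 20)
  sds <- apply(pd, 2, sd)
  expect_true(all(sds > 70 & sds < 130))
})

test_that("effect summaries follow their definition", {
  s <- effect_summary(matrix(log(2), 100, 1,
                             dimnames = list(NULL, "baby_log_or")))
  expect_equal(unlist(s[c("or_mean", "cri_low", "cri_high")],
                      use.names = FALSE), c(2, 2, 2))

  s2 <- effect_summary(matrix(c(log(1), log(4)), 2, 1,
                              dimnames = list(NULL, "baby_log_or")))
  expect_equal(s2$or_mean, 2.5)
  expect_gte(s2$cri_low, 1)
  expect_lte(s2$cri_high, 4)
})

test_that("emulated draws match the published interval they came from", {
  expect_equal((log(0.982) - log(0.774)) / (2 * qnorm(0.975)), 0.0607,
               tolerance = 1e-3)
  set.seed(14)
  d <- emulate_or_draws(0.774, 0.982, 1e6)
  q <- quantile(exp(d), c(0.025, 0.975), names = FALSE)
  expect_lt(abs(q[1] - 0.774) / 0.774, 0.005)
  expect_lt(abs(q[2] - 0.982) / 0.982, 0.005)
  # round-trip through the summary, including the mean OR
  s <- effect_summary(matrix(d, ncol = 1,
                             dimnames = list(NULL, "baby_log_or")))
  expect_equal(s$or_mean, 0.873, tolerance = 0.01)

  expect_equal(emulate_or_draws(1, 1, 5), rep(0, 5))
  expect_error(emulate_or_draws(-0.1, 0.9, 5), "positive")
  expect_error(emulate_or_draws(0.9, 0.8, 5), "exceed")
})
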