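test_that("ICERs match the published ratios and flag dominance", {
  ci <- cea_input("CI", 5348791, 67361)
  fi <- cea_input("FI", 5592212, 19901)
  expect_equal(icer(ci)$icer, 79.4, tolerance = 0.01)
  expect_equal(icer(fi)$icer, 281.0, tolerance = 0.01)
  expect_equal(icer(cea_input("FICI", 5470501, 37590))$icer, 145.5,
               tolerance = 0.01)

  # CI is cheaper and more effective than FI: strict dominance
  expect_equal(icer(ci, fi)$status, "reference dominates")
  expect_equal(icer(fi, ci)$status, "reference dominated")

  expect_warning(u <- icer(ci, cea_input("twin", 1, 67361)),
                 class = "mnhcea_undefined_icer")
  expect_true(is.na(u$icer))
  expect_equal(u$delta_cost, 5348791 - 1)
})

test_that("EIB is linear in k and zero at the ICER", {
  ci <- cea_input("CI", 5348791, 67361)
  expect_equal(eib(ci, 780), 780 * 67361 - 5348791) # 47,192,789
  expect_equal(eib(cea_input("FICI", 5470501, 37590), 780), 23849699)
  expect_equal(eib(ci, icer(ci)$icer), 0, tolerance = 1e-6)
  k <- c(0, 100, 500, 780)
  expect_equal(diff(eib(ci, k)) / diff(k), rep(67361, 3))
})

test_that("CEAC counts strict net-benefit wins over matched draws", {
  ref <- cea_input("A", 10, c(5, 6, 7))
  comp <- cea_input("B", 0, c(0, 0, 0))
  expect_equal(ceac(ref, comp, k = 1e6), 1)
  expect_equal(ceac(ref, comp, k = 0), 0) # cost decides at k = 0
  # two-draw toy with net benefits {10, -2} vs {0, 0}
  expect_equal(ceac(cea_input("r", 0, c(10, -2)),
                    cea_input("c", 0, c(0, 0)), k = 1), 0.5)
  # ties count as not more cost-effective
  expect_equal(ceac(cea_input("r", 0, c(1, 1)),
                    cea_input("c", 0, c(1, 0)), k = 1), 0.5)
  expect_error(ceac(cea_input("r", 0, 1:3), cea_input("c", 0, 1:2), k = 1),
               "equal draw counts")

  # complement property without ties
  set.seed(12)
  a <- cea_input("a", 100, rnorm(500))
  b <- cea_input("b", 90, rnorm(500))
  for (k in c(10, 100, 1000)) {
    expect_equal(ceac(a, b, k) + ceac(b, a, k), 1)
  }
})

test_that("EVPI equals hand enumeration and brute force, and is non-negative", {
  # E[max] = (10 + 4)/2 = 7, max(E) = 5, EVPI = 2
  expect_equal(evpi(list(cea_input("A", 0, c(10, 0)),
                         cea_input("B", 0, c(0, 4))), k = 1), 2)
  # an option better in every draw leaves no decision uncertainty
  expect_equal(evpi(list(cea_input("A", 0, c(3, 4, 5))), k = 1), 0)

  # brute-force oracle: explicit loops over draws and options
  evpi_brute <- function(costs, effects, k) {
    n <- nrow(effects)
    best_per_draw <- numeric(n)
    for (j in seq_len(n)) {
      nbj <- -Inf
      for (i in seq_len(ncol(effects))) {
        nbj <- max(nbj, k * effects[j, i] - costs[i])
      }
      best_per_draw[j] <- max(nbj, 0) # do-nothing
    }
    means <- numeric(ncol(effects))
    for (i in seq_len(ncol(effects))) {
      means[i] <- mean(k * effects[, i] - costs[i])
    }
    mean(best_per_draw) - max(c(means, 0))
  }
  set.seed(19)
  for (rep in 1:25) {
    n_opt <- sample(2:4, 1)
    n_draw <- sample(2:10, 1)
    costs <- runif(n_opt, 0, 50)
    effects <- matrix(rnorm(n_draw * n_opt, 0, 5), n_draw, n_opt)
    inputs <- lapply(seq_len(n_opt), function(i)
      cea_input(paste0("o", i), costs[i], effects[, i]))
    k <- runif(1, 0, 10)
    expect_equal(evpi(inputs, k), evpi_brute(costs, effects, k))
    expect_gte(evpi(inputs, k), 0)
  }
})

test_that("EVPI vanishes as the posterior concentrates", {
  eff <- trial_effects()
  row <- eff[eff$intervention == "CI", ]
  vals <- vapply(c(1, 0.3, 0.1, 0.01), function(shrink) {
    set.seed(2)
    mid <- sqrt(row$or_baby_lo * row$or_baby_hi)
    half <- (row$or_baby_hi / mid)^shrink
    pd <- cbind(
      baby_log_or = emulate_or_draws(mid / half, mid * half, 5000),
      mother_log_or = emulate_or_draws(0.99, 1.01, 5000))
    od <- convert_draws(pd, baseline_rates(0.05, 0.007))
    evpi(list(cea_input("CI", 5348791, od$dalys_averted)), k = 780)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_lt(vals[4], 1e-6 * vals[1])
})

test_that("the frontier prunes dominated and extended-dominated options", {
  # published means: FI dominated; FICI on the frontier vs CI
  ins <- list(cea_input("CI", 5348791, 67361),
              cea_input("FI", 5592212, 19901),
              cea_input("FICI", 10941002, 75180))
  fr <- ce_frontier(ins)
  expect_equal(fr$status[fr$label == "FI"], "dominated")
  expect_equal(fr$status[fr$label == "CI"], "frontier")
  expect_equal(fr$icer_vs_previous[fr$label == "FICI"],
               (10941002 - 5348791) / (75180 - 67361)) # 715.2
  expect_equal(fr$icer_vs_previous[fr$label == "CI"], 5348791 / 67361)

  # extended dominance: B's ICER exceeds the next step's
  ext <- ce_frontier(list(cea_input("A", 10, 1),
                          cea_input("B", 20, 10)))
  expect_equal(ext$status[ext$label == "A"], "extended dominated")
  expect_equal(ext$icer_vs_previous[ext$label == "B"], 2)

  # identical options collapse to one frontier point
  same <- ce_frontier(list(cea_input("A", 10, 5), cea_input("B", 10, 5),
                           cea_input("C", 10, 5)))
  expect_equal(sum(same$status == "frontier"), 1)
})

test_that("the cea object is internally consistent at published inputs", {
  eff <- trial_effects()
  draws <- lapply(c("CI", "FI", "FICI"), function(iv) {
    pd <- emulate_posterior(eff[eff$intervention == iv, ], 5000,
                            seed = match(iv, c("CI", "FI", "FICI")))
    row <- eff[eff$intervention == iv, ]
    p_b <- calibrate_p0(pd[, "baby_log_or"], row$babies_saved,
                        row$population)
    p_m <- calibrate_p0(pd[, "mother_log_or"], row$mothers_saved,
                        row$population)
    od <- convert_draws(pd, baseline_rates(p_b, p_m, 54000,
                                           row$population / 54000))
    cea_input(iv, row$total_cost, od$dalys_averted)
  })
  res <- cea(draws, k = threshold_grid(kmax = 1000, step = 50))
  expect_s3_class(res, "cea")
  expect_true(780 %in% res$k)
  expect_true(all(res$by_k$ceac >= 0 & res$by_k$ceac <= 1))
  expect_true(all(res$by_k$evpi >= 0))
  # per k, strict-best probabilities over all options sum to at most 1
  agg <- tapply(res$by_k$prob_best, res$by_k$k, sum)
  expect_true(all(agg <= 1 + 1e-12))
  # CEAC vs a zero-cost comparator is non-decreasing in k for C_ref > 0
  for (opt in c("CI", "FI", "FICI")) {
    cc <- res$by_k$ceac[res$by_k$option == opt]
    expect_true(all(diff(cc) >= 0))
  }
  s <- summary(res)
  expect_equal(s$option, c("CI", "FI", "FICI"))
  expect_equal(s$icer, c(79.4, 281.0, 145.5), tolerance = 0.05)
})
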