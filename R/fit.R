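#' MCMC configuration for the effect model
#'
#' The trial analysis saved 100,000 simulations: two chains of 510,000
#' iterations, a burn-in of 10,000 and thinning of 10. Those are the
#' defaults here; reduced schedules are fine for exploration and testing.
#'
#' @param chains Number of chains.
#' @param iterations Iterations per chain (including burn-in).
#' @param burnin Burn-in iterations discarded per chain; proposal adaptation
#'   happens only during burn-in.
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @return An object of class `mcmc_config`. The saved draw count is
#'   `chains * (iterations - burnin) / thin`.
#' @export
#' @examples
#' mcmc_config(chains = 2, iterations = 5000, burnin = 1000, thin = 2)
mcmc_config <- function(chains = 2, iterations = 510000, burnin = 10000,
                        thin = 10) {
  stopifnot(chains >= 1, iterations > burnin, burnin >= 1, thin >= 1)
  kept <- (iterations - burnin) / thin
  if (kept != floor(kept)) {
    stop("(iterations - burnin) must be a multiple of 'thin'", call. = FALSE)
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 n_saved = as.integer(chains * kept)),
            class = "mcmc_config")
}

## ---- internal: design matrix and likelihood ----

# Intercept + district dummies + urban dummy + treatment indicators.
# Dummies are built by hand so single-level factors (e.g. a one-district
# fixture) simply drop out instead of erroring.
build_design <- function(records, model) {
  records <- validate_cluster_records(records)
  if (model == "single") {
    records <- records[records$arm %in% c("control", "FICI"), , drop = FALSE]
    if (!any(records$arm == "FICI") || !any(records$arm == "control")) {
      stop("single-comparison model needs both FICI and control clusters",
           call. = FALSE)
    }
  }
  n <- nrow(records)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  dl <- sort(unique(records$district))
  if (length(dl) > 1) {
    for (d in dl[-1]) {
      X <- cbind(X, as.numeric(records$district == d))
      colnames(X)[ncol(X)] <- paste0("district", d)
    }
  }
  if (length(unique(records$stratum)) > 1) {
    X <- cbind(X, stratumurban = as.numeric(records$stratum == "urban"))
  }
  if (model == "factorial") {
    X <- cbind(X,
               CI = as.numeric(records$arm %in% c("CI", "FICI")),
               FI = as.numeric(records$arm %in% c("FI", "FICI")))
    trt <- c("CI", "FI")
  } else {
    X <- cbind(X, FICI = as.numeric(records$arm == "FICI"))
    trt <- "FICI"
  }
  list(X = X, records = records, treatments = trt)
}

# Binomial log-likelihood on the logit scale, safe at extreme eta.
loglik_binom <- function(eta, deaths, births) {
  # log p and log(1-p) via plogis log.p: numerically stable
  sum(deaths * stats::plogis(eta, log.p = TRUE) +
        (births - deaths) * stats::plogis(-eta, log.p = TRUE))
}

# Starting value and proposal covariance from a maximum-likelihood fit;
# falls back to zeros / identity when the glm is degenerate.
init_equation <- function(X, deaths, births) {
  p <- ncol(X)
  start <- rep(0, p)
  prop <- diag(p)
  keep <- births > 0
  if (sum(keep) >= p && sum(deaths) > 0 && any(deaths[keep] < births[keep])) {
    fit <- tryCatch(
      stats::glm.fit(X[keep, , drop = FALSE],
                     cbind(deaths[keep], births[keep] - deaths[keep]),
                     family = stats::binomial()),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$coefficients))) {
      start <- fit$coefficients
      v <- tryCatch(chol2inv(chol(crossprod(X[keep, , drop = FALSE] *
                                              sqrt(fit$weights)))),
                    error = function(e) NULL)
      if (!is.null(v) && all(is.finite(v))) prop <- v
    }
  }
  list(start = start, prop = prop)
}

# One chain of the adaptive random-walk Metropolis-within-Gibbs sampler.
# The baby and mother equations are the two Gibbs blocks; each block gets a
# multivariate-normal random-walk proposal whose scale follows a
# Robbins-Monro recursion toward 23.4% acceptance and whose shape is
# re-estimated from the burn-in history. Adaptation stops at the end of
# burn-in so the retained chain is Markovian.
run_chain <- function(X, deaths_list, births, prior_sd, cfg) {
  p <- ncol(X)
  ne <- length(deaths_list)
  ini <- lapply(deaths_list, function(d) init_equation(X, d, births))
  beta <- lapply(ini, `[[`, "start")
  chol_prop <- lapply(ini, function(z) {
    ch <- tryCatch(chol(z$prop + diag(1e-8, p)), error = function(e) diag(p))
    ch
  })
  log_s <- rep(log(2.38 / sqrt(p)), ne)
  eta <- lapply(beta, function(b) drop(X %*% b))
  lp <- vapply(seq_len(ne), function(e) {
    loglik_binom(eta[[e]], deaths_list[[e]], births) +
      sum(stats::dnorm(beta[[e]], 0, prior_sd, log = TRUE))
  }, numeric(1))

  n_keep <- (cfg$iterations - cfg$burnin) / cfg$thin
  kept <- lapply(seq_len(ne), function(e) matrix(NA_real_, n_keep, p))
  hist_b <- lapply(seq_len(ne), function(e)
    matrix(NA_real_, cfg$burnin, p))
  acc <- numeric(ne)
  ki <- 0L
  for (it in seq_len(cfg$iterations)) {
    adapting <- it <= cfg$burnin
    for (e in seq_len(ne)) {
      z <- drop(crossprod(chol_prop[[e]], stats::rnorm(p))) * exp(log_s[e])
      cand <- beta[[e]] + z
      eta_c <- eta[[e]] + drop(X %*% z)
      lp_c <- loglik_binom(eta_c, deaths_list[[e]], births) +
        sum(stats::dnorm(cand, 0, prior_sd, log = TRUE))
      a <- lp_c - lp[e]
      accepted <- is.finite(a) && log(stats::runif(1)) < a
      if (accepted) {
        beta[[e]] <- cand
        eta[[e]] <- eta_c
        lp[e] <- lp_c
        acc[e] <- acc[e] + 1
      }
      if (adapting) {
        g <- min(0.9, 5 / it^0.6)
        log_s[e] <- log_s[e] + g * ((if (accepted) 1 else 0) - 0.234)
        hist_b[[e]][it, ] <- beta[[e]]
        if (it %% 500 == 0 && it >= 1000) {
          h <- hist_b[[e]][seq(it %/% 2, it), , drop = FALSE]
          S <- stats::cov(h) + diag(1e-8, p)
          ch <- tryCatch(chol(S), error = function(err) NULL)
          if (!is.null(ch)) chol_prop[[e]] <- ch
        }
      }
    }
    if (it > cfg$burnin && (it - cfg$burnin) %% cfg$thin == 0) {
      ki <- ki + 1L
      for (e in seq_len(ne)) kept[[e]][ki, ] <- beta[[e]]
    }
  }
  for (e in seq_len(ne)) colnames(kept[[e]]) <- colnames(X)
  list(draws = kept, accept = acc / cfg$iterations)
}

## ---- internal: convergence diagnostics ----

split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_chain <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  # Geyer initial positive sequence on pairs
  s <- 0
  k <- 1
  while (k < length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

fit_diagnostics <- function(draw_mats, chains) {
  # draw_mats: list per equation of (saved x p) matrices, chains stacked
  out <- list()
  for (e in names(draw_mats)) {
    m <- draw_mats[[e]]
    per <- nrow(m) / chains
    for (j in colnames(m)) {
      xs <- lapply(seq_len(chains), function(c)
        m[(c - 1) * per + seq_len(per), j])
      out[[length(out) + 1]] <- data.frame(
        equation = e, parameter = j,
        rhat = split_rhat(xs),
        ess = sum(vapply(xs, ess_chain, numeric(1))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## ---- user-facing fit ----

#' Fit the Bayesian logistic effect model to cluster-level counts
#'
#' Fits two logistic regressions on cluster totals — combined stillbirth +
#' neonatal ("baby") deaths per birth and maternal ("mother") deaths per
#' birth — with intercept, district and urban/rural stratum covariates and
#' intervention indicators. The factorial model uses all four arms with CI
#' and FI main-effect indicators (CI is 1 in the CI and FICI arms, FI in the
#' FI and FICI arms, no interaction); the single-comparison model restricts
#' to the FICI and control arms with one indicator. Corresponding baby and
#' mother coefficients carry a bivariate normal prior with mean zero,
#' variance 10,000 per component on the log-odds scale and prior correlation
#' zero.
#'
#' Posterior draws come from a self-contained adaptive random-walk
#' Metropolis-within-Gibbs sampler (one Gibbs block per equation, proposal
#' scale and shape adapted during burn-in only), initialised at the
#' maximum-likelihood estimate when it exists. Convergence is checked with
#' split-chain potential scale reduction; values above 1.05 trigger a
#' warning, not an error.
#'
#' @param records Cluster records (the [simulate_trial()] schema).
#' @param model `"factorial"` or `"single"`.
#' @param prior_sd Prior standard deviation on the log-odds scale
#'   (default 100, i.e. variance 10,000).
#' @param mcmc An [mcmc_config()].
#' @param seed Integer seed for reproducible draws.
#' @return An object of class `mortality_fit` with methods `print`,
#'   `summary`, `coef` and `simulate`. Matched per-intervention draws of
#'   (baby log-OR, mother log-OR) are extracted with [posterior_draws()].
#' @seealso [posterior_draws()], [effect_summary()], [emulate_posterior()]
#' @export
#' @examples
#' trial <- simulate_trial(trial_design(n_clusters_per_arm = 6), seed = 1)
#' fit <- fit_mortality_model(trial, "factorial",
#'   mcmc = mcmc_config(chains = 2, iterations = 1500, burnin = 500),
#'   seed = 1)
#' summary(fit)
fit_mortality_model <- function(records,
                                model = c("factorial", "single"),
                                prior_sd = 100,
                                mcmc = mcmc_config(),
                                seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(mcmc, "mcmc_config"), prior_sd > 0)
  des <- build_design(records, model)
  if (model == "factorial") {
    arms <- unique(des$records$arm)
    if (length(unique(des$X[, "CI"])) < 2 ||
        length(unique(des$X[, "FI"])) < 2) {
      stop("factorial model needs variation in both CI and FI exposure; ",
           "arms present: ", paste(arms, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  deaths_list <- list(baby = des$records$baby_deaths,
                      mother = des$records$mother_deaths)
  chains <- lapply(seq_len(mcmc$chains), function(c)
    run_chain(des$X, deaths_list, des$records$births, prior_sd, mcmc))
  draws <- list(
    baby = do.call(rbind, lapply(chains, function(z) z$draws[[1]])),
    mother = do.call(rbind, lapply(chains, function(z) z$draws[[2]])))
  diag_df <- fit_diagnostics(draws, mcmc$chains)
  if (any(is.finite(diag_df$rhat) & diag_df$rhat > 1.05)) {
    worst <- diag_df[which.max(diag_df$rhat), ]
    warning(sprintf(
      "possible non-convergence: max split-Rhat %.3f (%s, %s equation)",
      worst$rhat, worst$parameter, worst$equation), call. = FALSE)
  }
  structure(list(model = model,
                 treatments = des$treatments,
                 draws = draws,
                 diagnostics = diag_df,
                 accept = rowMeans(vapply(chains, `[[`, numeric(2),
                                          "accept")),
                 mcmc = mcmc,
                 prior_sd = prior_sd,
                 design = des,
                 seed = seed,
                 call = match.call()),
            class = "mortality_fit")
}

#' Matched posterior odds-ratio draws for one intervention
#'
#' @param fit A [fit_mortality_model()] object.
#' @param intervention One of the fit's treatment labels (`"CI"`/`"FI"` for
#'   the factorial model, `"FICI"` for the single model).
#' @return A matrix of class `posterior_draws` with columns `baby_log_or`
#'   and `mother_log_or`, one row per saved simulation; baby and mother
#'   columns are jointly indexed (matched draws).
#' @export
posterior_draws <- function(fit, intervention = fit$treatments[1]) {
  stopifnot(inherits(fit, "mortality_fit"))
  if (!intervention %in% fit$treatments) {
    stop("intervention must be one of: ",
         paste(fit$treatments, collapse = ", "), call. = FALSE)
  }
  new_posterior_draws(fit$draws$baby[, intervention],
                      fit$draws$mother[, intervention],
                      intervention)
}

new_posterior_draws <- function(baby_log_or, mother_log_or, intervention) {
  m <- cbind(baby_log_or = baby_log_or, mother_log_or = mother_log_or)
  structure(m, intervention = intervention, class = c("posterior_draws",
                                                      class(m)))
}

#' @export
print.mortality_fit <- function(x, ...) {
  cat(sprintf("Bayesian cluster-level mortality model (%s)\n", x$model))
  cat(sprintf("  clusters: %d, saved draws: %d (%d chain%s)\n",
              nrow(x$design$records), nrow(x$draws$baby), x$mcmc$chains,
              if (x$mcmc$chains > 1) "s" else ""))
  cat(sprintf("  max split-Rhat: %.3f, min ESS: %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  print(summary(x), digits = 3)
  invisible(x)
}

#' @export
summary.mortality_fit <- function(object, ...) {
  rows <- lapply(object$treatments, function(trt) {
    s <- effect_summary(posterior_draws(object, trt))
    cbind(intervention = trt, s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.mortality_fit <- function(object, ...) {
  rbind(baby = colMeans(object$draws$baby),
        mother = colMeans(object$draws$mother))
}

#' Posterior-predictive simulation of cluster counts
#'
#' Draws new cluster-level death counts from the fitted model: for each
#' simulation a posterior coefficient draw is taken at random and binomial
#' counts generated at the observed births.
#'
#' @param object A `mortality_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data.frames with the cluster-record schema.
#' @export
simulate.mortality_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- object$design$X
  rec <- object$design$records
  idx <- sample.int(nrow(object$draws$baby), nsim, replace = TRUE)
  lapply(idx, function(i) {
    pb <- stats::plogis(drop(X %*% object$draws$baby[i, ]))
    pm <- stats::plogis(drop(X %*% object$draws$mother[i, ]))
    out <- rec
    out$baby_deaths <- stats::rbinom(nrow(rec), rec$births, pb)
    out$mother_deaths <- stats::rbinom(nrow(rec), rec$births, pm)
    out
  })
}

#' Summarise odds-ratio draws
#'
#' Posterior mean odds ratio and equal-tailed 95% credible interval
#' (empirical 2.5th and 97.5th centiles) per outcome.
#'
#' @param draws A [posterior_draws()] matrix, or any matrix/vector of
#'   log-odds-ratio draws.
#' @return A `data.frame` with columns `outcome`, `or_mean`, `cri_low`,
#'   `cri_high`.
#' @export
#' @examples
#' effect_summary(cbind(baby_log_or = rnorm(1000, log(0.9), 0.05),
#'                      mother_log_or = rnorm(1000, 0, 0.3)))
effect_summary <- function(draws) {
  m <- as.matrix(draws)
  if (is.null(colnames(m))) colnames(m) <- paste0("lor", seq_len(ncol(m)))
  rows <- lapply(colnames(m), function(cn) {
    or <- exp(m[, cn])
    q <- stats::quantile(or, c(0.025, 0.975), names = FALSE)
    data.frame(outcome = sub("_log_or$", "", cn),
               or_mean = mean(or), cri_low = q[1], cri_high = q[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emulate posterior log-odds-ratio draws from a published summary
#'
#' When only a posterior summary (mean odds ratio and 95% credible interval)
#' is available, draws are reconstructed from a lognormal whose 2.5th and
#' 97.5th quantiles match the interval: on the log scale, location
#' `(log lo + log hi)/2` and scale `(log hi - log lo)/3.92`. The implied
#' mean odds ratio `exp(location + scale^2/2)` may differ slightly from the
#' published mean; the reconstruction matches the interval, not the mean.
#' A degenerate interval (`lo == hi`) yields constant draws.
#'
#' @param cri_low,cri_high Published 2.5th/97.5th centiles of the odds
#'   ratio; must be positive.
#' @param n_draws Number of draws.
#' @return Numeric vector of log-odds-ratio draws.
#' @seealso [emulate_posterior()] for matched baby/mother draws.
#' @export
emulate_or_draws <- function(cri_low, cri_high, n_draws) {
  if (cri_low <= 0 || cri_high <= 0) {
    stop("credible-interval bounds must be positive", call. = FALSE)
  }
  if (cri_low > cri_high) stop("cri_low must not exceed cri_high",
                               call. = FALSE)
  loc <- (log(cri_low) + log(cri_high)) / 2
  scl <- (log(cri_high) - log(cri_low)) / (2 * stats::qnorm(0.975))
  if (scl == 0) return(rep(loc, n_draws))
  stats::rnorm(n_draws, loc, scl)
}

#' Emulate matched baby/mother posterior draws from published summaries
#'
#' Builds a [posterior_draws()] matrix for one intervention from the
#' published odds-ratio credible intervals (see [trial_effects()]), drawing
#' the baby and mother log odds ratios independently — the joint posterior
#' correlation in the original model run is not recoverable from the
#' summaries, which is a documented caveat of this emulation.
#'
#' @param summary_row One row of [trial_effects()] (or a list with elements
#'   `intervention`, `or_baby_lo`, `or_baby_hi`, `or_mother_lo`,
#'   `or_mother_hi`).
#' @param n_draws Number of matched draws.
#' @param seed Optional seed.
#' @return A `posterior_draws` matrix.
#' @export
#' @examples
#' eff <- trial_effects()
#' pd <- emulate_posterior(eff[eff$intervention == "CI", ], 1000, seed = 1)
#' effect_summary(pd)
emulate_posterior <- function(summary_row, n_draws, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  new_posterior_draws(
    emulate_or_draws(summary_row$or_baby_lo, summary_row$or_baby_hi,
                     n_draws),
    emulate_or_draws(summary_row$or_mother_lo, summary_row$or_mother_hi,
                     n_draws),
    summary_row$intervention)
}
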