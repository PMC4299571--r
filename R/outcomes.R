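#' DALY weights per death averted
#'
#' Years of life lost per averted death, with no age-weighting and no
#' discounting. The standard variant uses the reference life table: 86.0
#' years per baby (stillbirth or neonatal death, all stillbirths assumed
#' viable) and 53.27 years per mother (remaining life expectancy of a woman
#' aged 30, the median age of maternal death). The localised variant uses
#' Malawi-specific healthy life expectancies: 45.0 and 28.1 years.
#'
#' @param variant `"standard"` or `"localised"`.
#' @return A list with elements `per_baby`, `per_mother`, `variant`.
#' @export
daly_weights <- function(variant = c("standard", "localised")) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    list(per_baby = 86.0, per_mother = 53.27, variant = variant)
  } else {
    list(per_baby = 45.0, per_mother = 28.1, variant = variant)
  }
}

#' Baseline (control-area) mortality rates and comparison population
#'
#' The conversion from odds ratios to deaths averted needs the control-area
#' death probabilities and the number of births covered by the comparison:
#' 54,000 births per arm, with two arms for the CI and FI comparisons and
#' one for FICI vs control.
#'
#' @param baby_p0 Control probability of combined stillbirth/neonatal death
#'   per birth.
#' @param mother_p0 Control probability of maternal death per birth.
#' @param births_per_arm Births per arm over the trial period.
#' @param arms Arms in the comparison (2 for CI/FI, 1 for FICI).
#' @return An object of class `baseline_rates`; the comparison population is
#'   `births_per_arm * arms`.
#' @export
baseline_rates <- function(baby_p0, mother_p0, births_per_arm = 54000,
                           arms = 2) {
  stopifnot(baby_p0 > 0, baby_p0 < 1, mother_p0 > 0, mother_p0 < 1,
            births_per_arm > 0, arms %in% c(1, 2))
  structure(list(baby_p0 = baby_p0, mother_p0 = mother_p0,
                 births_per_arm = births_per_arm, arms = arms,
                 population = births_per_arm * arms),
            class = "baseline_rates")
}

#' Deaths averted implied by an odds ratio
#'
#' Applies the odds ratio to the control odds to get the intervention-area
#' death probability, then multiplies the risk difference by the population:
#' `p1 = or * odds0 / (1 + or * odds0)` with `odds0 = p0/(1-p0)`, returning
#' `n * (p0 - p1)`. Negative values mean deaths added (odds ratio above 1).
#'
#' @param or Odds ratio draw(s); vectorised.
#' @param p0 Control-area death probability.
#' @param n Population (births) the comparison covers.
#' @return Signed deaths averted, same length as `or`.
#' @export
#' @examples
#' deaths_averted(0.8, 0.05, 54000)
deaths_averted <- function(or, p0, n) {
  stopifnot(all(or > 0), p0 > 0, p0 < 1, n > 0)
  odds0 <- p0 / (1 - p0)
  p1 <- or * odds0 / (1 + or * odds0)
  n * (p0 - p1)
}

#' DALYs averted from deaths averted
#'
#' Linear combination of baby and mother deaths averted with the DALY
#' weights; no age weights, no discounting.
#'
#' @param babies_saved,mothers_saved Signed deaths averted (vectorised).
#' @param weights A [daly_weights()] list.
#' @return DALYs averted (years).
#' @export
to_dalys <- function(babies_saved, mothers_saved,
                     weights = daly_weights()) {
  stopifnot(weights$per_baby > 0, weights$per_mother > 0)
  babies_saved * weights$per_baby + mothers_saved * weights$per_mother
}

#' Convert posterior odds-ratio draws to outcome draws
#'
#' Applies the OR-to-deaths-averted conversion and the DALY weights to every
#' saved simulation, preserving the matched draw indexing.
#'
#' @param draws A [posterior_draws()] matrix (columns `baby_log_or`,
#'   `mother_log_or`).
#' @param base A [baseline_rates()].
#' @param weights A [daly_weights()].
#' @return A `data.frame` of class `outcome_draws` with columns `draw`,
#'   `babies_saved`, `mothers_saved`, `dalys_averted`; attributes
#'   `intervention` and `population`.
#' @export
#' @examples
#' pd <- emulate_posterior(trial_effects()[1, ], 1000, seed = 1)
#' od <- convert_draws(pd, baseline_rates(0.05, 0.007))
#' colMeans(od[-1])
convert_draws <- function(draws, base, weights = daly_weights()) {
  stopifnot(inherits(base, "baseline_rates"))
  m <- as.matrix(draws)
  babies <- deaths_averted(exp(m[, "baby_log_or"]), base$baby_p0,
                           base$population)
  mothers <- deaths_averted(exp(m[, "mother_log_or"]), base$mother_p0,
                            base$population)
  out <- data.frame(draw = seq_len(nrow(m)),
                    babies_saved = babies,
                    mothers_saved = mothers,
                    dalys_averted = to_dalys(babies, mothers, weights))
  attr(out, "intervention") <- attr(draws, "intervention")
  attr(out, "population") <- base$population
  class(out) <- c("outcome_draws", class(out))
  out
}

#' Double outcome draws to two-arm parity
#'
#' The one-arm FICI comparison covers half the population of the two-arm CI
#' and FI comparisons; doubling effects (and, separately, costs) puts all
#' three options on the same population. The doubling is explicit, never
#' implicit.
#'
#' @param outcomes An `outcome_draws` data.frame.
#' @return The draws with all outcome columns doubled and the population
#'   attribute updated.
#' @export
double_outcomes <- function(outcomes) {
  stopifnot(inherits(outcomes, "outcome_draws"))
  out <- outcomes
  for (cn in c("babies_saved", "mothers_saved", "dalys_averted")) {
    out[[cn]] <- 2 * out[[cn]]
  }
  attr(out, "population") <- 2 * attr(outcomes, "population")
  out
}

#' Calibrate a control-area death probability to a target mean
#'
#' The published tables report mean deaths averted but not the control-area
#' probabilities behind them. This reconstructs a probability by bisection:
#' it finds `p0` such that the mean of [deaths_averted()] over the supplied
#' odds-ratio draws equals the target. Used to rebuild outcome draws from
#' published summaries; the result is a reconstruction, not observed data.
#'
#' @param log_or_draws Log odds-ratio draws.
#' @param target_mean_saved Target mean deaths averted.
#' @param n Comparison population.
#' @param interval Search interval for `p0`.
#' @return The calibrated probability.
#' @export
calibrate_p0 <- function(log_or_draws, target_mean_saved, n,
                         interval = c(1e-6, 0.5)) {
  or <- exp(log_or_draws)
  f <- function(p0) mean(deaths_averted(or, p0, n)) - target_mean_saved
  # mean averted is monotone in p0 for a fixed OR cloud on one side of 1;
  # uniroot handles the general case
  stats::uniroot(f, interval, tol = 1e-12)$root
}
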