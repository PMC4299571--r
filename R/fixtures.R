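#' Published cost structure of the trial interventions
#'
#' Cost components of the community intervention (CI), the facility quality
#' improvement intervention (FI) and their combination (FICI), in constant
#' 2013 international dollars, as reported for the 27-month Malawi trial.
#' `FICI` covers one arm; `FICI2` is the doubled two-arm version used when
#' comparing all three options over the same population.
#'
#' @return A named list of [cost_summary()] objects
#'   (`CI`, `FI`, `FICI`, `FICI2`).
#' @seealso [trial_effects()], [malawi_context()]
#' @export
#' @examples
#' sapply(trial_costs(), trial_total_cost)
trial_costs <- function() {
  ci <- cost_summary("CI", 362083, 2068997, 27250, 120067, arms_covered = 2L)
  fi <- cost_summary("FI", 362860, 2026811, 25328, 272017, arms_covered = 2L)
  fici <- cost_summary("FICI", 362472, 2047904, 26289, 196042,
                       arms_covered = 1L)
  list(CI = ci, FI = fi, FICI = fici, FICI2 = rescale_arms(fici, 2L))
}

#' Published posterior effect summaries of the trial interventions
#'
#' Posterior means and 95% credible intervals for the odds ratios of
#' combined stillbirth + neonatal ("baby") mortality and maternal ("mother")
#' mortality, and for the derived deaths and DALYs averted, per intervention.
#' `population` is the number of babies (equally, mothers) in the relevant
#' comparison over the 27-month trial period: 108,000 for the two-arm CI and
#' FI comparisons and for the doubled FICI2 row, 54,000 for one-arm FICI.
#' `total_cost` is the matching trial-period intervention cost.
#'
#' @return A `data.frame`, one row per intervention
#'   (CI, FI, FICI, FICI2).
#' @export
trial_effects <- function() {
  data.frame(
    intervention = c("CI", "FI", "FICI", "FICI2"),
    population = c(108000, 108000, 54000, 108000),
    total_cost = c(5348791, 5592212, 5470501, 10941002),
    or_baby = c(0.873, 0.954, 0.841, 0.841),
    or_baby_lo = c(0.774, 0.846, 0.707, 0.707),
    or_baby_hi = c(0.982, 1.070, 0.992, 0.992),
    or_mother = c(0.957, 1.228, 1.287, 1.287),
    or_mother_lo = c(0.494, 0.652, 0.488, 0.488),
    or_mother_hi = c(1.657, 2.135, 2.839, 2.839),
    babies_saved = c(772, 291, 475, 951),
    babies_saved_lo = c(109, -439, 23, 46),
    babies_saved_hi = c(1384, 974, 880, 1760),
    mothers_saved = c(18, -97, -62, -124),
    mothers_saved_lo = c(-270, -480, -397, -793),
    mothers_saved_hi = c(210, 148, 112, 223),
    dalys_averted = c(67361, 19901, 37590, 75180),
    dalys_averted_lo = c(8808, -44769, -4642, -9284),
    dalys_averted_hi = c(121508, 80586, 74618, 149236),
    stringsAsFactors = FALSE
  )
}

#' National context for scale-up and affordability
#'
#' Demographic and expenditure figures framing the affordability analysis.
#' Defaults describe Malawi in 2010: total population, crude birth rate
#' (births per person-year), annual per-capita health expenditure in
#' constant 2013 international dollars, and the share of health expenditure
#' spent on maternal and neonatal health (MNH). `trial_population` is the
#' estimated resident population of the two trial arms each intervention
#' covered, used to form the trial-to-nation scaling ratio.
#'
#' @param population Total national population.
#' @param crude_birth_rate Births per person per year.
#' @param per_capita_health_exp Annual per-capita health expenditure ($).
#' @param mnh_share Proportion of health expenditure spent on MNH.
#' @param trial_population Resident population covered by a two-arm
#'   intervention area.
#' @param threshold Reference willingness-to-pay ($ per DALY averted);
#'   default 780, the 2013 per-capita GDP.
#' @return An object of class `national_context`.
#' @export
#' @examples
#' ctx <- malawi_context()
#' mnh_budget(ctx)
malawi_context <- function(population = 15013694,
                           crude_birth_rate = 0.04,
                           per_capita_health_exp = 228.7,
                           mnh_share = 0.1195,
                           trial_population = 1200000,
                           threshold = 780) {
  stopifnot(population > 0, crude_birth_rate > 0,
            per_capita_health_exp > 0,
            mnh_share > 0, mnh_share < 1, trial_population > 0)
  structure(list(population = population,
                 crude_birth_rate = crude_birth_rate,
                 per_capita_health_exp = per_capita_health_exp,
                 mnh_share = mnh_share,
                 trial_population = trial_population,
                 threshold = threshold),
            class = "national_context")
}
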