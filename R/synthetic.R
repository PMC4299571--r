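#' Design configuration for a synthetic 2x2 factorial cluster trial
#'
#' Describes the study conditions emulated by [simulate_trial()]: a
#' two-by-two factorial cluster-randomised trial of a community intervention
#' (CI) and a facility intervention (FI) with four arms (control, CI, FI,
#' FICI), cluster-level binomial mortality counts, and small fixed district
#' and urban/rural covariate effects on the log-odds scale.
#'
#' Defaults mirror the Malawi trial the package models: roughly 15 clusters
#' per arm, 54,000 births per arm over a 2.25-year period, a control-arm
#' combined stillbirth + neonatal death probability of 0.05 and a maternal
#' death probability of 0.007 (consistent with rural Malawi around 2010),
#' and intervention odds ratios equal to the posterior means reported for
#' the trial.
#'
#' @param n_clusters_per_arm Clusters per arm.
#' @param districts Character vector of district labels.
#' @param p_urban Probability a cluster is urban.
#' @param births_per_arm Total births per arm over the trial period.
#' @param trial_years Trial period length in years.
#' @param baseline_baby_prob Control-arm probability of combined stillbirth
#'   or neonatal death per birth.
#' @param baseline_mother_prob Control-arm probability of maternal death per
#'   birth (one mother per birth).
#' @param or_baby,or_mother Named vectors of true odds ratios for arms
#'   `CI`, `FI` and `FICI` (baby and mother outcomes).
#' @param district_effects Log-odds offsets per district (recycled to the
#'   number of districts).
#' @param stratum_effect Log-odds offset applied to urban clusters.
#' @param cluster_sd Standard deviation of normal cluster-level
#'   perturbations of the log-odds (overdispersion); 0 gives exact binomial
#'   cluster counts.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_clusters_per_arm = 15,
                         districts = c("Lilongwe", "Kasungu", "Salima"),
                         p_urban = 0.1,
                         births_per_arm = 54000,
                         trial_years = 2.25,
                         baseline_baby_prob = 0.05,
                         baseline_mother_prob = 0.007,
                         or_baby = c(CI = 0.873, FI = 0.954, FICI = 0.841),
                         or_mother = c(CI = 0.957, FI = 1.228, FICI = 1.287),
                         district_effects = c(0, 0.05, -0.05),
                         stratum_effect = -0.05,
                         cluster_sd = 0.1) {
  stopifnot(n_clusters_per_arm >= 1, length(districts) >= 1,
            p_urban >= 0, p_urban <= 1,
            births_per_arm >= n_clusters_per_arm,
            trial_years > 0,
            baseline_baby_prob > 0, baseline_baby_prob < 1,
            baseline_mother_prob > 0, baseline_mother_prob < 1,
            all(or_baby > 0), all(or_mother > 0), cluster_sd >= 0)
  for (nm in c("CI", "FI", "FICI")) {
    if (!nm %in% names(or_baby) || !nm %in% names(or_mother)) {
      stop("odds ratios must be named for arms CI, FI and FICI",
           call. = FALSE)
    }
  }
  structure(list(n_clusters_per_arm = as.integer(n_clusters_per_arm),
                 districts = districts,
                 p_urban = p_urban,
                 births_per_arm = as.integer(births_per_arm),
                 trial_years = trial_years,
                 baseline_baby_prob = baseline_baby_prob,
                 baseline_mother_prob = baseline_mother_prob,
                 or_baby = or_baby, or_mother = or_mother,
                 district_effects = rep_len(district_effects,
                                            length(districts)),
                 stratum_effect = stratum_effect,
                 cluster_sd = cluster_sd),
            class = "trial_design")
}

#' Simulate cluster-level data from a factorial trial design
#'
#' Births are split near-equally across the clusters of each arm
#' (multinomial jitter); cluster death counts are binomial with probability
#' `plogis(qlogis(baseline) + log OR(arm) + district effect + stratum effect
#' + cluster perturbation)`. The same seed always reproduces the same data.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed; if `NULL` the current RNG state is used.
#' @return A `data.frame` with columns `cluster_id`, `district`, `stratum`,
#'   `arm`, `births`, `baby_deaths`, `mother_deaths`.
#' @export
#' @examples
#' trial <- simulate_trial(trial_design(), seed = 1)
#' arm_totals(trial)
simulate_trial <- function(design = trial_design(), seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  arms <- c("control", "CI", "FI", "FICI")
  k <- design$n_clusters_per_arm
  recs <- lapply(arms, function(arm) {
    births <- as.vector(stats::rmultinom(1, design$births_per_arm,
                                         rep(1 / k, k)))
    district <- sample(design$districts, k, replace = TRUE)
    stratum <- ifelse(stats::runif(k) < design$p_urban, "urban", "rural")
    d_eff <- design$district_effects[match(district, design$districts)]
    s_eff <- ifelse(stratum == "urban", design$stratum_effect, 0)
    pert <- if (design$cluster_sd > 0) {
      stats::rnorm(k, 0, design$cluster_sd)
    } else {
      rep(0, k)
    }
    lor <- if (arm == "control") c(baby = 0, mother = 0) else {
      c(baby = log(design$or_baby[[arm]]),
        mother = log(design$or_mother[[arm]]))
    }
    p_baby <- stats::plogis(stats::qlogis(design$baseline_baby_prob) +
                              lor[["baby"]] + d_eff + s_eff + pert)
    p_mother <- stats::plogis(stats::qlogis(design$baseline_mother_prob) +
                                lor[["mother"]] + d_eff + s_eff + pert)
    data.frame(cluster_id = sprintf("%s_%02d", arm, seq_len(k)),
               district = district,
               stratum = stratum,
               arm = arm,
               births = births,
               baby_deaths = stats::rbinom(k, births, p_baby),
               mother_deaths = stats::rbinom(k, births, p_mother),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Check a cluster-records table
#'
#' @param records A `data.frame` of cluster records (the [simulate_trial()]
#'   schema).
#' @return The validated `data.frame`, invisibly usable downstream.
#' @export
validate_cluster_records <- function(records) {
  need <- c("cluster_id", "district", "stratum", "arm", "births",
            "baby_deaths", "mother_deaths")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("cluster records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0) stop("no cluster records", call. = FALSE)
  with(records, {
    if (any(births < 0 | baby_deaths < 0 | mother_deaths < 0)) {
      stop("counts must be non-negative", call. = FALSE)
    }
    if (any(baby_deaths > births) || any(mother_deaths > births)) {
      stop("deaths cannot exceed births in a cluster", call. = FALSE)
    }
  })
  records
}

#' Per-arm totals of births and deaths
#'
#' @param records Cluster records (see [simulate_trial()]).
#' @return A `data.frame` with one row per arm: total births, baby deaths,
#'   mother deaths, and crude death probabilities.
#' @export
arm_totals <- function(records) {
  records <- validate_cluster_records(records)
  agg <- stats::aggregate(
    records[c("births", "baby_deaths", "mother_deaths")],
    by = list(arm = records$arm), FUN = sum)
  agg$p_baby <- agg$baby_deaths / agg$births
  agg$p_mother <- agg$mother_deaths / agg$births
  agg
}
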