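# Shared fixtures built in code.

# A short MCMC schedule for tests; the full trial schedule is a default of
# mcmc_config(), not a test requirement.
test_mcmc <- function(chains = 2, iterations = 3000, burnin = 1000,
                      thin = 1) {
  mcmc_config(chains = chains, iterations = iterations, burnin = burnin,
              thin = thin)
}

# Eight hand-written clusters spanning all four arms; totals are easy to
# check by hand.
hand_clusters <- function() {
  data.frame(
    cluster_id = paste0("c", 1:8),
    district = rep(c("A", "B"), 4),
    stratum = c("rural", "urban", "rural", "rural",
                "urban", "rural", "rural", "rural"),
    arm = rep(c("control", "CI", "FI", "FICI"), each = 2),
    births = c(100, 200, 150, 250, 120, 180, 160, 240),
    baby_deaths = c(5, 8, 6, 9, 7, 6, 5, 8),
    mother_deaths = c(1, 2, 0, 1, 2, 1, 1, 0),
    stringsAsFactors = FALSE)
}

# A null design: no intervention effects, no covariate effects, no
# cluster-level heterogeneity.
null_design <- function(n_clusters_per_arm = 4, births_per_arm = 6000) {
  trial_design(n_clusters_per_arm = n_clusters_per_arm,
               births_per_arm = births_per_arm,
               or_baby = c(CI = 1, FI = 1, FICI = 1),
               or_mother = c(CI = 1, FI = 1, FICI = 1),
               district_effects = c(0, 0, 0),
               stratum_effect = 0,
               cluster_sd = 0)
}

# The published cost components, as plain numbers, for arithmetic checks.
published_costs <- function() {
  list(CI = c(start_up = 362083, imp = 2068997, mnt = 27250, ext = 120067,
              total = 5348791, annual = 2216315),
       FI = c(start_up = 362860, imp = 2026811, mnt = 25328, ext = 272017,
              total = 5592212, annual = 2324156),
       FICI1 = c(start_up = 362472, imp = 2047904, mnt = 26289,
                 ext = 196042, total = 5470501),
       FICI2 = c(start_up = 724943, imp = 4095808, mnt = 52578,
                 ext = 392084, total = 10941002, annual = 4540471))
}
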