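# Published mean binding parameters for the fluorescent VEGF isoforms at
# NanoLuc-tagged VEGFR2 and NRP1, used as simulation ground truths.
# kon in M^-1 min^-1, koff in min^-1, KD in nM.
truth <- list(
  vegfr2_165a = list(sat_kd_nM = 2.03, kon = 1.54e7, koff = 0.06),
  vegfr2_165b = list(sat_kd_nM = 9.53, kon = 7.29e6, koff = 0.06),
  vegfr2_121a = list(sat_kd_nM = 5.54, kon = 8.51e6, koff = 0.05),
  nrp1_165a   = list(sat_kd_nM = 4.41, kon = 7.11e7, koff = 0.26,
                     pki_165a = 9.54)
)

rates_vegfr2 <- function() kinetic_rates(truth$vegfr2_165a$kon,
                                         truth$vegfr2_165a$koff)
rates_nrp1 <- function() kinetic_rates(truth$nrp1_165a$kon,
                                       truth$nrp1_165a$koff)

# standard simulated designs at the published study conditions
sat_design <- function(kd_nM, noise_sd = NULL, n_experiments = 5,
                       seed = 1, bmax = 0.02, baseline = 0.05,
                       ns_slope = 0) {
  simulation_design(
    "saturation",
    eq_binding_params(kd = kd_nM * 1e-9, bmax = bmax, ns_slope = ns_slope,
                      baseline = baseline),
    probe_concs_nM = c(0.1, 0.3, 1, 3, 5, 10, 20, 30),
    noise_sd = noise_sd, n_experiments = n_experiments, seed = seed)
}

assoc_design <- function(rates, noise_sd = NULL, n_experiments = 5,
                         seed = 1, replicates = 1, bmax = 0.02,
                         baseline = 0.05) {
  simulation_design(
    "association",
    list(rates = rates, bmax = bmax, baseline = baseline),
    probe_concs_nM = c(1, 2.5, 5, 10, 20),
    timepoints_min = seq(0, 20, by = 0.5),
    replicates = replicates, noise_sd = noise_sd,
    n_experiments = n_experiments, seed = seed)
}

comp_design <- function(ki_M, probe_kd_nM, noise_sd = NULL,
                        n_experiments = 5, seed = 1,
                        probe_concs_nM = c(0.5, 1, 2, 3, 5)) {
  simulation_design(
    "competition",
    list(probe = eq_binding_params(kd = probe_kd_nM * 1e-9, bmax = 0.02,
                                   ns_slope = 0, baseline = 0.05),
         ki = ki_M),
    probe_concs_nM = probe_concs_nM,
    competitor_concs_nM = c(0, 10^seq(-3, 2, by = 0.5)),
    noise_sd = noise_sd, n_experiments = n_experiments, seed = seed)
}

# Monte-Carlo oracle: empirical rejection rate of the two-sample pooled
# t test over simulated experiments (vectorised over replicates).
mc_power_ttest <- function(reps, n, sd, delta, alpha = 0.05, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(reps * n, 0, sd), nrow = reps)
  y <- matrix(stats::rnorm(reps * n, delta, sd), nrow = reps)
  vx <- apply(x, 1, stats::var)
  vy <- apply(y, 1, stats::var)
  sp <- sqrt((vx + vy) / 2)
  tstat <- (rowMeans(y) - rowMeans(x)) / (sp * sqrt(2 / n))
  mean(abs(tstat) > stats::qt(1 - alpha / 2, 2 * n - 2))
}
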