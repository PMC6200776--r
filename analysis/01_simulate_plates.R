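#!/usr/bin/env Rscript
# Simulate the four plate designs of the live-cell NanoBRET binding study
# at the published ground truths (5 independent experiments, duplicate
# wells, additive ratio-scale noise at 5% of the specific amplitude), and
# write the long-format plate CSVs consumed by the downstream fit scripts.

suppressPackageStartupMessages(library(bretfit))
seed <- 20181018L
out <- "results/plates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# saturation: fluorescent VEGF165a at NanoLuc-VEGFR2 (KD 2.03 nM) and
# NanoLuc-NRP1 (KD 4.41 nM), paired 100 nM-unlabeled NSB wells
for (rec in list(list(tag = "vegfr2", kd = 2.03), list(tag = "nrp1", kd = 4.41))) {
  tab <- simulate_plate(simulation_design(
    "saturation",
    eq_binding_params(kd = rec$kd * 1e-9, bmax = 0.02, ns_slope = 1e5,
                      baseline = 0.05),
    probe_concs_nM = c(0.1, 0.3, 1, 3, 5, 10, 20, 30), seed = seed))
  write_plate_csv(tab, file.path(out, sprintf("saturation_%s.csv", rec$tag)))
}

# association: 1-20 nM probe, reads every 30 s for 20 min, vehicle wells
rates <- list(vegfr2 = kinetic_rates(1.54e7, 0.06),
              nrp1 = kinetic_rates(7.11e7, 0.26))
for (tag in names(rates)) {
  tab <- simulate_plate(simulation_design(
    "association",
    list(rates = rates[[tag]], bmax = 0.02, baseline = 0.05),
    probe_concs_nM = c(1, 2.5, 5, 10, 20),
    timepoints_min = seq(0, 20, by = 0.5), replicates = 2, seed = seed))
  write_plate_csv(tab, file.path(out, sprintf("association_%s.csv", tag)))
}

# competition: unlabeled VEGF165a vs 0.5-5 nM probe at NanoLuc-NRP1
comp <- simulate_plate(simulation_design(
  "competition",
  list(probe = eq_binding_params(kd = 4.41e-9, bmax = 0.02, ns_slope = 0,
                                 baseline = 0.05),
       ki = 10^-9.54),
  probe_concs_nM = c(0.5, 1, 2, 3, 5),
  competitor_concs_nM = c(0, 10^seq(-3, 2, by = 0.5)), seed = seed))
write_plate_csv(comp, file.path(out, "competition_nrp1.csv"))

# concentration-response: NFAT reporter activation, pEC50 8.16
cr <- simulate_plate(simulation_design(
  "concentration_response",
  cr_params(ec50 = 10^-8.16, emax = 100, basal = 2),
  probe_concs_nM = c(0, 10^seq(-1.5, 3, by = 0.5)), seed = seed))
write_plate_csv(cr, file.path(out, "nfat_cr.csv"))

for (f in list.files(out, full.names = TRUE))
  cat(sprintf("%-40s %5d wells\n", f, nrow(read_plate_csv(f))))
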