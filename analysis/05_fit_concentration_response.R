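#!/usr/bin/env Rscript
# Concentration-response fit of the simulated NFAT reporter data:
# sigmoidal curve with unit Hill slope, pEC50 reported per experiment and
# aggregated. Expected to recover pEC50 near 8.16.

suppressPackageStartupMessages(library(bretfit))
dir.create("results", showWarnings = FALSE)

tab <- read_plate_csv("results/plates/nfat_cr.csv")
fit <- fit_concentration_response(tab)
cat(sprintf("NFAT response: pEC50 = %.2f +/- %.2f, Emax = %.1f (n = %d)\n",
            fit$mean[["pec50"]], fit$sem[["pec50"]], fit$mean[["emax"]],
            fit$n))
write.csv(data.frame(pec50 = fit$mean[["pec50"]],
                     pec50_sem = fit$sem[["pec50"]],
                     ec50_nM = fit$mean[["ec50_nM"]],
                     emax = fit$mean[["emax"]],
                     basal = fit$mean[["basal"]],
                     n_experiments = fit$n),
          "results/concentration_response_summary.csv", row.names = FALSE)
cat("wrote results/concentration_response_summary.csv\n")
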