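#!/usr/bin/env Rscript
# Monte-Carlo comparison of 10 mg/kg Q2W versus 10 mg/kg Q3W dosing:
# 500 simulation iterations, body weights drawn from the trial's weight
# distribution, per-iteration random effects, noise-free profiles over 21
# weeks, pointwise 5th/50th/95th percentile bands.
# Writes results/regimen_bands.csv and results/regimen_summary.csv.

suppressPackageStartupMessages(library(ramerpk))

pop <- default_pop_parameters()
regs <- list(q2w = regimen(interval = 336, dose_per_kg = 10, n_doses = 10),
             q3w = regimen(interval = 504, dose_per_kg = 10, n_doses = 7))
grid <- sort(unique(c(seq(0, 3528, by = 4), 336 * (0:9) + 1,
                      504 * (0:6) + 1)))
res <- simulate_regimen_comparison(pop, regs, n_iter = 500,
                                   weight_sampler = default_weight_sampler(),
                                   seed = 42, grid = grid)

dir.create("results", showWarnings = FALSE)
bands <- do.call(rbind, lapply(names(regs), function(nm) {
  data.frame(regimen = nm, time_h = res$grid,
             p5 = res[[nm]]$bands["p5", ], p50 = res[[nm]]$bands["p50", ],
             p95 = res[[nm]]$bands["p95", ])
}))
write.csv(bands, "results/regimen_bands.csv", row.names = FALSE)

summary_tab <- data.frame(
  regimen = names(regs),
  median_ss_trough = sapply(names(regs), function(nm)
    res[[nm]]$median_ss_trough),
  median_cmax = sapply(names(regs), function(nm) res[[nm]]$median_cmax))
write.csv(summary_tab, "results/regimen_summary.csv", row.names = FALSE)

cat("500-iteration regimen comparison (10 mg/kg):\n")
print(summary_tab, digits = 4, row.names = FALSE)
cat(sprintf("\nQ2W median steady-state trough exceeds Q3W by %.1f ug/mL (%.0f%%)\n",
            summary_tab$median_ss_trough[1] - summary_tab$median_ss_trough[2],
            100 * (summary_tab$median_ss_trough[1] /
                     summary_tab$median_ss_trough[2] - 1)))
cat(sprintf("median Cmax ratio Q2W/Q3W: %.3f\n",
            summary_tab$median_cmax[1] / summary_tab$median_cmax[2]))
frac <- mean(res$q2w$bands["p5", res$grid >= 336 * 9] > 50)
cat(sprintf("Q2W 5th-percentile band above 50 ug/mL over the final cycle: %s\n",
            ifelse(frac == 1, "yes", sprintf("%.0f%% of the time", 100 * frac))))
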