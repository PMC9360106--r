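#!/usr/bin/env Rscript
# Exposure-efficacy analysis of the virtual trial: univariate Cox with
# continuous Cmin,1, stepwise covariate selection, quartile-versus-control
# adjusted hazard ratios with Kaplan-Meier medians, and the Mahalanobis
# caliper matched case-control sensitivity analysis.
# Requires results/trial/ from analysis/02_simulate_trial.R.
# Writes results/hr_table.csv, results/km_medians.csv,
# results/matched_balance.csv.

suppressPackageStartupMessages(library(ramerpk))

if (!file.exists("results/trial/subjects.csv"))
  stop("run analysis/02_simulate_trial.R first")
subj <- read.csv("results/trial/subjects.csv")
expo <- exposure_records(read.csv("results/trial/exposures.csv"))

subj$time <- subj$pfs_months
subj$event <- subj$pfs_event
subj$female <- as.integer(subj$sex == "female")
subj$exon21 <- as.integer(subj$egfr == "Exon21")
subj$east_asia <- as.integer(subj$region == "EastAsia")
subj$ever_smoker <- as.integer(subj$smoking == "ever")
subj$liver_met <- as.integer(subj$liver_met)
subj$age65 <- as.integer(subj$age >= 65)

treated <- merge(subj[subj$arm == "RAM+ERL" & !subj$excluded, ],
                 expo, by = "id")
treated$quartile <- treated$quartile_cmin1
control <- subj[subj$arm == "PBO+ERL", ]

# univariate continuous exposure effect within the treated arm
uni <- cox_fit(treated, "cmin1")
cat(sprintf("univariate Cox, continuous Cmin,1: HR/ug/mL %.4f (95%% CI %.4f-%.4f), p = %.3f\n",
            uni$hr, uni$ci_lower, uni$ci_upper, uni$p))

# stepwise prognostic-factor selection on the pooled analysis population
candidates <- c("ecog", "female", "exon21", "east_asia", "ever_smoker",
                "liver_met", "age65")
pooled <- rbind(treated[c("time", "event", candidates)],
                control[c("time", "event", candidates)])
adjusters <- stepwise_select(pooled, candidates)
cat("stepwise-selected prognostic factors:",
    if (length(adjusters)) paste(adjusters, collapse = ", ") else "(none)",
    "\n")

res <- quartile_hr_analysis(treated, control, adjusters)
write.csv(res$hr_table, "results/hr_table.csv", row.names = FALSE)
cat("\nquartile-versus-control adjusted hazard ratios:\n")
print(res$hr_table, digits = 3, row.names = FALSE)

med <- data.frame(group = names(res$km),
                  median_pfs_months = sapply(res$km, function(k) k$median),
                  n = sapply(res$km, function(k) k$n_risk[1]))
write.csv(med, "results/km_medians.csv", row.names = FALSE)
cat("\nKaplan-Meier median PFS (months):\n")
print(med, digits = 3, row.names = FALSE)

# matched case-control sensitivity analysis on the selected factors plus age
factors <- unique(c(adjusters, "age65", "ecog"))
matched <- matched_quartile_analysis(treated, control, factors)
bal <- do.call(rbind, lapply(names(matched), function(q) {
  b <- matched[[q]]$balance
  b$quartile <- q
  b$n_pairs <- nrow(matched[[q]]$matched$pairs)
  b$hr_matched <- if (!is.null(matched[[q]]$cox))
    matched[[q]]$cox$hr[["trt"]] else NA_real_
  b
}))
write.csv(bal, "results/matched_balance.csv", row.names = FALSE)
cat("\nmatched analysis balance (pre/post p-values) and matched HRs:\n")
print(bal, digits = 3, row.names = FALSE)
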