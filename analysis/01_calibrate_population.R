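#!/usr/bin/env Rscript
# Calibration of the default population PK parameters.
#
# Structural values (V1, V2, Q, allometric exponents, Emax/t50/hill, the
# non-clearance omega entries, residual SDs) are fixed at
# literature-plausible monoclonal-antibody values.  The typical clearance
# and the clearance IIV are tuned so that a simulated 10 mg/kg Q2W
# population reproduces the reported steady-state trough summary
# (geometric mean 85.7 ug/mL, natural-scale CV 32%).  This script evaluates
# a small local grid around the shipped defaults with common random numbers
# and then verifies the shipped defaults at n = 1000; it writes
# results/calibration_grid.csv and results/calibration_check.csv.

suppressPackageStartupMessages(library(ramerpk))

simulate_cminss <- function(pop, weights, etas) {
  reg <- regimen(interval = 336, dose_per_kg = 10, n_doses = 14)
  vapply(seq_along(weights), function(i) {
    ind <- individual_parameters(pop, weights[i], etas[i, ])
    trough_at_steady_state(ind, pop, reg)
  }, numeric(1))
}

build_pop <- function(cl_typical, sd_cl) {
  base <- default_pop_parameters()
  omega <- base$omega
  scale <- sd_cl / sqrt(omega[1, 1])
  omega[1, ] <- omega[1, ] * scale
  omega[, 1] <- omega[, 1] * scale
  pop_parameters(cl_typical = cl_typical, v1_typical = base$v1_typical,
                 v2_typical = base$v2_typical, q_typical = base$q_typical,
                 wt_exp_cl = base$wt_exp_cl, wt_exp_v1 = base$wt_exp_v1,
                 wt_ref = base$wt_ref, emax_typical = base$emax_typical,
                 t50 = base$t50, hill = base$hill, omega = omega,
                 sigma_prop = base$sigma_prop, sigma_add = base$sigma_add)
}

dir.create("results", showWarnings = FALSE)
target_geo <- 85.7
target_cv <- 32

# -- local grid with common random numbers -------------------------------
set.seed(20260801)
n_grid <- 500
w <- default_weight_sampler()(n_grid)
z <- matrix(rnorm(n_grid * 4), n_grid, 4)  # standard normals, rescaled below

grid <- expand.grid(cl_typical = c(0.0180, 0.0184, 0.0188),
                    sd_cl = c(0.17, 0.195, 0.22))
grid$geomean <- NA_real_
grid$cv_pct <- NA_real_
for (i in seq_len(nrow(grid))) {
  pop_i <- build_pop(grid$cl_typical[i], grid$sd_cl[i])
  eg <- eigen(pop_i$omega, symmetric = TRUE)
  root <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0))) %*% t(eg$vectors)
  css <- simulate_cminss(pop_i, w, z %*% root)
  s <- summarize_exposure(css)
  grid$geomean[i] <- s$geomean
  grid$cv_pct[i] <- s$cv_pct
}
grid$geo_err_pct <- 100 * (grid$geomean / target_geo - 1)
grid$cv_err_pp <- grid$cv_pct - target_cv
write.csv(grid, "results/calibration_grid.csv", row.names = FALSE)
cat("Local calibration grid (common random numbers, n =", n_grid, "):\n")
print(grid, digits = 4)

# -- verification of the shipped defaults --------------------------------
pop <- default_pop_parameters()
check <- do.call(rbind, lapply(c(11, 12, 13), function(seed) {
  set.seed(seed)
  n <- 1000
  css <- simulate_cminss(pop, default_weight_sampler()(n),
                         sample_etas(pop, n))
  s <- summarize_exposure(css)
  data.frame(seed = seed, n = n, geomean = s$geomean, cv_pct = s$cv_pct,
             pct_above_50 = 100 * fraction_above(css, 50),
             p5 = s$p5, min = s$min, max = s$max)
}))
write.csv(check, "results/calibration_check.csv", row.names = FALSE)
cat("\nShipped defaults at n = 1000 (targets: geomean 85.7, CV 32%):\n")
print(check, digits = 4)
cat(sprintf("\nmax |geomean error| %.2f%%, max |CV error| %.2f pp\n",
            max(abs(100 * (check$geomean / target_geo - 1))),
            max(abs(check$cv_pct - target_cv))))
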