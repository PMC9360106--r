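#' Calibrated default population parameters
#'
#' The package's default population for the weight-based 10 mg/kg Q2W
#' antibody regimen.  Structural and variability parameters other than
#' clearance (V1, V2, Q, the allometric exponents, the clearance-versus-time
#' Emax/t50/hill, and the non-clearance omega entries) are fixed at
#' literature-plausible values for an IgG1 monoclonal antibody; the typical
#' clearance and its inter-individual variance were calibrated by simulation
#' (see \code{analysis/01_calibrate_population.R}) so that the simulated
#' steady-state trough distribution under 10 mg/kg Q2W reproduces the
#' reported geometric mean (85.7 ug/mL) and natural-scale CV (32%) to within
#' 2%.  The calibrated values are simulation-derived defaults, not published
#' estimates.
#'
#' @return a [pop_parameters()] object.
#' @export
default_pop_parameters <- function() {
  sd_cl <- 0.195
  sd_v1 <- 0.20
  sd_v2 <- 0.40
  sd_emax <- 0.08
  omega <- diag(c(sd_cl, sd_v1, sd_v2, sd_emax)^2)
  omega[1, 2] <- omega[2, 1] <- 0.4 * sd_cl * sd_v1
  omega[1, 4] <- omega[4, 1] <- 0.3 * sd_cl * sd_emax
  pop_parameters(
    cl_typical = 0.0184,
    v1_typical = 5.5,
    v2_typical = 2.9,
    q_typical = 0.023,
    wt_exp_cl = 0.54,
    wt_exp_v1 = 0.46,
    wt_ref = 60.8,
    emax_typical = -0.25,
    t50 = 720,
    hill = 2,
    omega = omega,
    sigma_prop = 0.15,
    sigma_add = 1
  )
}

#' Default weight sampler matching the trial population
#'
#' Truncated lognormal body-weight sampler (mean 60.8 kg, 22% CV, bounds
#' 35.8-117.0 kg).
#'
#' @return a function(n) returning n weights in kg.
#' @export
default_weight_sampler <- function() {
  cfg <- default_covariate_config()$weight
  function(n) .sample_trunc_lnorm(n, cfg$mean, cfg$cv, cfg$min, cfg$max)
}
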