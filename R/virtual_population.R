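#' Default covariate configuration for the virtual trial
#'
#' Frequencies and moments emulating the baseline demographics of a
#' first-line EGFR-mutant NSCLC population dosed with a weight-based
#' antibody: body weight lognormal with mean 60.8 kg and 22% CV truncated to
#' 35.8-117.0 kg, 63% female, ECOG performance status 0/1 split 53/47,
#' EGFR Exon19/Exon21 split 53/47, 76% East-Asian region, smoking history
#' ever/never/unknown 32/62/6, 11% liver metastasis, age mean 62.9 (SD 10.6)
#' truncated to 23-89 years.
#'
#' @return a list of covariate settings consumed by [sample_subjects()].
#' @export
default_covariate_config <- function() {
  list(
    weight = list(mean = 60.8, cv = 0.22, min = 35.8, max = 117.0),
    age = list(mean = 62.9, sd = 10.6, min = 23, max = 89),
    p_female = 0.63,
    p_ecog0 = 0.53,
    p_exon19 = 0.53,
    p_east_asia = 0.76,
    p_smoking = c(ever = 0.32, never = 0.62, unknown = 0.06),
    p_liver_met = 0.11
  )
}

# moment-matched lognormal on the untruncated scale, then rejection-sampled
# into the configured bounds
.sample_trunc_lnorm <- function(n, mean, cv, lo, hi) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

.sample_trunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Sample baseline subjects
#'
#' Draws \code{n} subjects' baseline covariates from the configured marginal
#' distributions (covariates are generated independently).  No dosing,
#' exposure or outcome fields are filled here.
#'
#' @param n number of subjects (>= 0).
#' @param config covariate configuration, see [default_covariate_config()].
#' @param seed optional integer seed.
#' @return data.frame with columns \code{id}, \code{weight}, \code{age},
#'   \code{sex}, \code{ecog}, \code{egfr}, \code{region}, \code{smoking},
#'   \code{liver_met}.
#' @export
sample_subjects <- function(n, config = default_covariate_config(),
                            seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(config$p_smoking) - 1) > 1e-8)
    stop("smoking frequencies must sum to 1")
  if (n == 0) {
    return(data.frame(id = integer(), weight = numeric(), age = numeric(),
                      sex = character(), ecog = integer(), egfr = character(),
                      region = character(), smoking = character(),
                      liver_met = logical()))
  }
  w <- config$weight
  a <- config$age
  data.frame(
    id = seq_len(n),
    weight = .sample_trunc_lnorm(n, w$mean, w$cv, w$min, w$max),
    age = .sample_trunc_norm(n, a$mean, a$sd, a$min, a$max),
    sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    ecog = ifelse(stats::runif(n) < config$p_ecog0, 0L, 1L),
    egfr = ifelse(stats::runif(n) < config$p_exon19, "Exon19", "Exon21"),
    region = ifelse(stats::runif(n) < config$p_east_asia, "EastAsia", "Other"),
    smoking = sample(names(config$p_smoking), n, replace = TRUE,
                     prob = config$p_smoking),
    liver_met = stats::runif(n) < config$p_liver_met,
    stringsAsFactors = FALSE
  )
}

#' Sample individual random effects
#'
#' Multivariate-normal draws with mean zero and covariance \code{pop$omega}
#' (a possibly singular PSD matrix; zero-variance components are exactly 0).
#'
#' @param pop a [pop_parameters()] object.
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return an n x 4 matrix with columns CL, V1, V2, EMAX.
#' @export
sample_etas <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pop_parameters"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  eg <- eigen(pop$omega, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  root <- eg$vectors %*% diag(sqrt(lam), 4) %*% t(eg$vectors)
  z <- matrix(stats::rnorm(n * 4), n, 4)
  etas <- z %*% root
  colnames(etas) <- c("CL", "V1", "V2", "EMAX")
  etas
}

#' Default dose-modification configuration
#'
#' Stochastic dose adjustments emulating toxicity management on study: each
#' post-baseline dose independently risks a delay (mean 7 days, capped at 42)
#' and each subject may step down the 10 -> 8 -> 6 -> 5 mg/kg reduction
#' ladder.  The default per-dose rates give about three quarters of subjects
#' at least one dose adjustment over a 14-cycle course, matching the
#' trial-reported 76% of treated subjects with an antibody dose adjustment.
#'
#' @return a list with \code{p_delay}, \code{delay_mean_h}, \code{p_reduce}.
#' @export
default_modification_config <- function() {
  list(p_delay = 0.10, delay_mean_h = 168, p_reduce = 0.02)
}

#' Generate a subject's dosing history
#'
#' Expands the regimen for a subject's weight and applies random dose delays
#' and ladder reductions according to \code{mod_config}.  Amounts are
#' \code{dose_per_kg * weight}; reductions apply from the affected dose
#' onward (never re-escalating); delays shift the affected and all subsequent
#' doses; per-dose delays are capped at 42 days.
#'
#' @param subject one-row data.frame with a \code{weight} column (kg).
#' @param reg a [regimen()] object.
#' @param mod_config see [default_modification_config()]; \code{NULL} for no
#'   modifications.
#' @param seed optional integer seed.
#' @return a \code{dose_events} data.frame.
#' @export
generate_dosing_history <- function(subject, reg,
                                    mod_config = default_modification_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mods <- list()
  if (!is.null(mod_config)) {
    ladder <- c(8, 6, 5)
    step <- 0
    for (i in 2:reg$n_doses) {
      if (stats::runif(1) < mod_config$p_delay) {
        d <- min(stats::rexp(1, 1 / mod_config$delay_mean_h), 1008)
        mods[[length(mods) + 1]] <- list(dose = i, delay_h = d)
      }
      if (step < 3 && stats::runif(1) < mod_config$p_reduce) {
        step <- step + 1
        mods[[length(mods) + 1]] <- list(dose = i, dose_per_kg = ladder[step])
      }
    }
  }
  reg2 <- regimen(interval = reg$interval, dose_per_kg = reg$dose_per_kg,
                  n_doses = reg$n_doses, duration = reg$duration,
                  modifications = mods)
  dose_events(reg2, subject$weight)
}

#' Protocol PK sampling times
#'
#' The sparse clinical sampling schedule: pre-infusion troughs at cycles 1,
#' 2, 4, 7 and 14, one-hour post-infusion samples at cycles 1 and 14, and a
#' 30-day post-discontinuation follow-up visit, mapped onto a subject's
#' actual dose history.  Cycles beyond the administered doses are dropped.
#'
#' @param doses a \code{dose_events} data.frame.
#' @param followup_h follow-up offset after the last dose, h (default 720 =
#'   30 days).
#' @return data.frame with columns \code{time} (h) and \code{label}.
#' @export
protocol_sampling_times <- function(doses, followup_h = 720) {
  n <- nrow(doses)
  trough_cycles <- c(1, 2, 4, 7, 14)
  post_cycles <- c(1, 14)
  out <- data.frame(time = numeric(), label = character())
  for (cy in trough_cycles[trough_cycles <= n])
    out <- rbind(out, data.frame(time = doses$start[cy],
                                 label = sprintf("pre_c%d", cy)))
  for (cy in post_cycles[post_cycles <= n])
    out <- rbind(out, data.frame(time = doses$start[cy] + doses$duration[cy],
                                 label = sprintf("post_c%d", cy)))
  out <- rbind(out, data.frame(time = doses$start[n] + followup_h,
                               label = "followup"))
  out[order(out$time), ]
}

#' Draw protocol-sparse noisy observations
#'
#' Evaluates the subject's noise-free concentration profile at the protocol
#' sampling times and perturbs it with the combined residual-error model
#' \code{y = f * (1 + eps_prop) + eps_add}.  Negative draws are truncated at
#' zero and flagged.
#'
#' @param ind an [individual_parameters()] object.
#' @param pop a [pop_parameters()] object.
#' @param doses a \code{dose_events} data.frame.
#' @param seed optional integer seed.
#' @param followup_h follow-up offset, h.
#' @return a \code{concentration_profile} with \code{kind = "observation"},
#'   \code{labels}, and a logical \code{truncated} attribute.
#' @export
sparse_sample_observations <- function(ind, pop, doses, seed = NULL,
                                       followup_h = 720) {
  if (!is.null(seed)) set.seed(seed)
  sched <- protocol_sampling_times(doses, followup_h)
  pred <- solve_concentrations(ind, pop, doses, sched$time)$values
  k <- length(pred)
  y <- pred * (1 + stats::rnorm(k, 0, pop$sigma_prop)) +
    stats::rnorm(k, 0, pop$sigma_add)
  truncated <- y < 0
  y[truncated] <- 0
  structure(list(times = sched$time, values = y, kind = "observation",
                 labels = sched$label),
            truncated = truncated, class = "concentration_profile")
}

#' Outcome-generating scenario
#'
#' Defines the data-generating process for progression-free survival (PFS)
#' and graded adverse events, with configurable exposure dependence so both
#' null and alternative exposure-response hypotheses can be simulated.
#' The PFS hazard for subject i is
#' \code{h_i(t) = h_0(t) * exp(trt_i * log_hr_treatment +
#' trt_i * log_hr_exposure * (cmin1_i - exposure_ref) + x_i' covariate_log_hrs)},
#' with exponential censoring at \code{censor_rate} and administrative
#' censoring at \code{admin_censor_months}.  Exposure enters centred at
#' \code{exposure_ref} so the treatment effect is identified at a typical
#' exposure.  \code{ae_models} is a named list (term -> list(alpha =
#' cutpoint intercepts for grade >= 1 and grade >= 3, beta = slope per
#' ug/mL of Cmin,ss, trt_offset = additive treated-arm log-odds shift)).
#'
#' @param baseline_hazard exponential event rate, 1/month (or
#'   \code{list(shape=, scale=)} for Weibull).
#' @param log_hr_treatment treated-vs-control log hazard ratio.
#' @param log_hr_exposure log hazard ratio per ug/mL of Cmin,1 (0 = null
#'   exposure-response).
#' @param covariate_log_hrs named numeric vector of log HRs on covariate
#'   columns (\code{ecog}, \code{liver_met}, ... coerced to numeric).
#' @param censor_rate exponential dropout censoring rate, 1/month.
#' @param admin_censor_months administrative censoring horizon, months.
#' @param exposure_ref centring constant, ug/mL.
#' @param ae_models named list of ordinal AE generators (see Details).
#' @return an object of class \code{outcome_scenario}.
#' @export
outcome_scenario <- function(baseline_hazard = 0.045,
                             log_hr_treatment = log(0.6),
                             log_hr_exposure = 0,
                             covariate_log_hrs = c(ecog = 0.35),
                             censor_rate = 0.01,
                             admin_censor_months = 36,
                             exposure_ref = 37,
                             ae_models = default_ae_models()) {
  if (is.numeric(baseline_hazard) && baseline_hazard < 0)
    stop("rates must be >= 0")
  if (censor_rate < 0) stop("rates must be >= 0")
  structure(list(baseline_hazard = baseline_hazard,
                 log_hr_treatment = log_hr_treatment,
                 log_hr_exposure = log_hr_exposure,
                 covariate_log_hrs = covariate_log_hrs,
                 censor_rate = censor_rate,
                 admin_censor_months = admin_censor_months,
                 exposure_ref = exposure_ref,
                 ae_models = ae_models),
            class = "outcome_scenario")
}

#' Default adverse-event generating models
#'
#' Cumulative-logit generators for the safety terms tabulated in the
#' exposure-safety analysis, parameterised to reproduce the reported
#' control-arm and treated-arm incidences at a typical steady-state trough of
#' about 90 ug/mL with no exposure dependence (beta = 0, the null
#' exposure-safety hypothesis).  \code{alpha} holds the control-arm log-odds
#' of grade >= 1 and grade >= 3.
#'
#' @return named list of AE model parameter lists.
#' @export
default_ae_models <- function() {
  list(
    # alpha chosen so control / treated any-grade and grade>=3 incidences
    # land near the reported arm-level rates
    hypertension = list(alpha = c(qlogis(0.12), qlogis(0.05)),
                        trt_offset = c(1.85, 1.85), beta = 0),
    diarrhea = list(alpha = c(qlogis(0.30), qlogis(0.013)),
                    trt_offset = c(1.0, 1.75), beta = 0),
    dermatitis_acneiform = list(alpha = c(qlogis(0.55), qlogis(0.09)),
                                trt_offset = c(0.7, 0.6), beta = 0),
    proteinuria = list(alpha = c(qlogis(0.08), qlogis(0.002)),
                       trt_offset = c(1.8, 2.6), beta = 0),
    alt_increased = list(alpha = c(qlogis(0.31), qlogis(0.02)),
                         trt_offset = c(0.52, 0), beta = 0),
    ast_increased = list(alpha = c(qlogis(0.26), qlogis(0.02)),
                         trt_offset = c(0.72, 0), beta = 0)
  )
}

# draw a worst grade (0, 1-2 coded 1, >=3 coded 3) from a cumulative-logit
# model: logit P(grade >= k) = alpha_k + trt_offset_k * trt + beta * exposure
.draw_grade <- function(n, model, trt, exposure) {
  lp1 <- model$alpha[1] + model$trt_offset[1] * trt + model$beta * exposure
  lp3 <- model$alpha[2] + model$trt_offset[2] * trt + model$beta * exposure
  p1 <- stats::plogis(lp1)
  p3 <- pmin(stats::plogis(lp3), p1)  # cumulative probabilities must nest
  u <- stats::runif(n)
  ifelse(u < p3, 3L, ifelse(u < p1, 1L, 0L))
}

#' Simulate trial outcomes
#'
#' Fills PFS and adverse-event outcomes for a subject table under an
#' [outcome_scenario()]: exponential (or Weibull) PFS under the scenario's
#' proportional-hazards model with independent exponential plus
#' administrative censoring, and per-term worst grades from the scenario's
#' cumulative-logit AE models.
#'
#' @param subjects data.frame from [sample_subjects()] with an \code{arm}
#'   column (\code{"RAM+ERL"} or \code{"PBO+ERL"}).
#' @param exposures data.frame with \code{id}, \code{cmin1}, \code{cminss}
#'   for treated subjects (ignored, may be NA, for placebo).
#' @param scenario an [outcome_scenario()].
#' @param seed optional integer seed.
#' @return \code{subjects} with added columns \code{pfs_months},
#'   \code{pfs_event}, and one \code{grade_<term>} column per AE model.
#' @export
simulate_outcomes <- function(subjects, exposures, scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(scenario, "outcome_scenario"))
  n <- nrow(subjects)
  trt <- as.integer(subjects$arm == "RAM+ERL")
  idx <- match(subjects$id, exposures$id)
  cmin1 <- exposures$cmin1[idx]
  cminss <- exposures$cminss[idx]
  excl <- if ("excluded" %in% names(subjects)) subjects$excluded else
    rep(FALSE, n)
  if (any(trt == 1 & !excl & (is.na(cmin1) | is.na(cminss))))
    stop("missing exposure for a treated subject")
  # centred exposure term vanishes for controls and excluded subjects
  cmin1[trt == 0 | excl] <- scenario$exposure_ref
  cminss[trt == 0 | excl] <- 0
  lp <- trt * scenario$log_hr_treatment +
    trt * scenario$log_hr_exposure * (cmin1 - scenario$exposure_ref)
  for (nm in names(scenario$covariate_log_hrs))
    lp <- lp + scenario$covariate_log_hrs[[nm]] * as.numeric(subjects[[nm]])
  if (is.list(scenario$baseline_hazard)) {
    sh <- scenario$baseline_hazard$shape
    sc <- scenario$baseline_hazard$scale
    # Weibull PH: S(t) = exp(-(t/scale)^shape * exp(lp))
    t_event <- sc * (stats::rexp(n) / exp(lp))^(1 / sh)
  } else {
    t_event <- stats::rexp(n, rate = scenario$baseline_hazard * exp(lp))
  }
  t_cens <- if (scenario$censor_rate > 0)
    stats::rexp(n, rate = scenario$censor_rate) else rep(Inf, n)
  t_cens <- pmin(t_cens, scenario$admin_censor_months)
  subjects$pfs_months <- pmax(pmin(t_event, t_cens), 1e-6)
  subjects$pfs_event <- t_event <= t_cens
  for (term in names(scenario$ae_models)) {
    subjects[[paste0("grade_", term)]] <-
      .draw_grade(n, scenario$ae_models[[term]], trt, cminss)
  }
  subjects
}

#' Simulate a complete two-arm virtual trial
#'
#' End-to-end generator: randomises subjects 1:1-ish to treated
#' (\code{n_treated}) and control (\code{n_control}) arms, draws covariates
#' and PK random effects, builds dosing histories with stochastic dose
#' modifications (placebo subjects get zero-amount infusions), predicts
#' per-subject noise-free Cmin,1 and Cmin,ss, draws protocol-sparse noisy
#' observations, and simulates PFS/AE outcomes.  Trial flow is emulated by
#' marking \code{n_not_treated} randomized treated subjects as never dosed
#' and a further \code{n_no_pk} as having no evaluable PK; the analysis
#' population is randomized minus excluded.
#'
#' @param n_treated,n_control randomized arm sizes.
#' @param pop a [pop_parameters()] object (default [default_pop_parameters()]).
#' @param reg treated-arm [regimen()].
#' @param scenario an [outcome_scenario()].
#' @param covariate_config see [default_covariate_config()].
#' @param mod_config see [default_modification_config()]; \code{NULL}
#'   disables dose modifications.
#' @param n_not_treated,n_no_pk treated-arm exclusion counts emulated.
#' @param seed integer seed for the whole trial.
#' @return list with \code{subjects} (all randomized, with \code{arm},
#'   \code{excluded}, \code{exclusion_reason}, outcomes), \code{exposures}
#'   (analysis-population treated subjects), \code{doses} (named list of
#'   \code{dose_events}), \code{observations} (named list of profiles), and
#'   \code{analysis_ids}.
#' @export
simulate_trial <- function(n_treated = 224, n_control = 225,
                           pop = default_pop_parameters(),
                           reg = regimen(interval = 336, dose_per_kg = 10,
                                         n_doses = 14),
                           scenario = outcome_scenario(),
                           covariate_config = default_covariate_config(),
                           mod_config = default_modification_config(),
                           n_not_treated = 3, n_no_pk = 5,
                           seed = 1) {
  set.seed(seed)
  n <- n_treated + n_control
  subjects <- sample_subjects(n, covariate_config)
  subjects$arm <- rep(c("RAM+ERL", "PBO+ERL"), c(n_treated, n_control))
  subjects$excluded <- FALSE
  subjects$exclusion_reason <- NA_character_
  trt_ids <- subjects$id[subjects$arm == "RAM+ERL"]
  drop_ids <- sample(trt_ids, n_not_treated + n_no_pk)
  nt <- drop_ids[seq_len(n_not_treated)]
  np <- setdiff(drop_ids, nt)
  subjects$excluded[subjects$id %in% drop_ids] <- TRUE
  subjects$exclusion_reason[subjects$id %in% nt] <- "not_treated"
  subjects$exclusion_reason[subjects$id %in% np] <- "no_evaluable_pk"

  etas <- sample_etas(pop, n)
  doses <- list()
  observations <- list()
  expo <- data.frame(id = integer(), cmin1 = numeric(), cminss = numeric())
  for (i in seq_len(n)) {
    s <- subjects[i, ]
    if (s$arm == "PBO+ERL" || s$exclusion_reason %in% "not_treated") {
      ev <- dose_events(regimen(interval = reg$interval, dose_per_kg = 0,
                                n_doses = reg$n_doses,
                                duration = reg$duration), s$weight)
      ev$amount <- 0
      doses[[as.character(s$id)]] <- ev
      next
    }
    ind <- individual_parameters(pop, s$weight, etas[i, ])
    ev <- generate_dosing_history(s, reg, mod_config)
    doses[[as.character(s$id)]] <- ev
    if (!s$excluded) {
      observations[[as.character(s$id)]] <-
        sparse_sample_observations(ind, pop, ev)
      expo <- rbind(expo, data.frame(
        id = s$id,
        cmin1 = trough_after_first_dose(ind, pop, reg),
        cminss = trough_at_steady_state(ind, pop, reg, doses = ev)))
    }
  }
  analysis_ids <- subjects$id[!subjects$excluded]
  subjects <- simulate_outcomes(subjects, expo, scenario)
  list(subjects = subjects, exposures = expo, doses = doses,
       observations = observations, analysis_ids = analysis_ids)
}
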