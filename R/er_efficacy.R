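#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function with median and its
#' log-log (Brookmeyer-Crowley-style) confidence interval, computed with
#' \pkg{survival}.  Subjects censored at an event time are counted at risk
#' for that event (the standard convention).
#'
#' @param records data.frame with columns \code{time} (months, > 0) and
#'   \code{event} (logical or 0/1).
#' @return a \code{km_curve}: list with \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}, \code{median}, \code{median_ci}
#'   (length-2, may be NA) and the underlying \code{survfit} object.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stop("need at least one record")
  if (any(records$time <= 0)) stop("survival times must be positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log")
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  ci <- unname(c(stats::quantile(fit, probs = 0.5)$lower,
                 stats::quantile(fit, probs = 0.5)$upper))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = med, median_ci = ci,
                 fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events, median %s months\n",
              x$n_risk[1], sum(x$n_event),
              ifelse(is.na(x$median), "not reached", format(x$median))))
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by partial-likelihood maximisation (\pkg{survival},
#' Newton-Raphson) and reports hazard ratios with Wald 95% confidence
#' intervals \code{exp(coef +- 1.96 se)} and Wald p-values.  Efron tie
#' handling is the default; Breslow is available behind the \code{ties}
#' flag.  Monotone-likelihood separation is reported via the fit's
#' coefficient magnitude check.
#'
#' @param records data.frame with \code{time}, \code{event} and the model
#'   covariates.
#' @param covariates character vector of covariate column names.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return a \code{cox_fit}: list with \code{coef}, \code{se}, \code{hr},
#'   \code{ci_lower}, \code{ci_upper}, \code{p}, \code{loglik}, \code{ties},
#'   \code{n}, \code{n_event}, \code{separation} and the underlying
#'   \code{coxph} object.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(records$event) < 1) stop("need at least one event")
  for (cv in covariates) {
    x <- records[[cv]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("constant covariate: ", cv)
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = records, ties = ties)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- any(abs(beta) > 15)
  if (separation)
    warning("possible monotone likelihood (separation): |coef| > 15")
  structure(list(coef = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = fit$loglik[2], ties = ties,
                 n = fit$n, n_event = fit$nevent,
                 separation = separation, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d subjects, %d events\n",
              x$ties, x$n, x$n_event))
  tab <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci_lower,
                    upper95 = x$ci_upper, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Stepwise Cox covariate selection
#'
#' Iterated forward-addition / backward-elimination on Wald p-values:
#' each cycle adds the candidate with the smallest p-value below
#' \code{p_enter}, then drops the included covariate with the largest
#' p-value at or above \code{p_exit}, until the selected set is stable.
#' Records with missing values in any candidate are dropped (complete-case).
#' Deterministic given the data; an iteration cap guards against cycling.
#'
#' @param records survival data.frame.
#' @param candidates character vector of candidate covariate names.
#' @param p_enter entry threshold (default 0.05).
#' @param p_exit exit threshold (default 0.10).
#' @param max_iter iteration cap.
#' @return character vector of selected covariates (possibly empty).
#' @export
stepwise_select <- function(records, candidates, p_enter = 0.05,
                            p_exit = 0.10, max_iter = 50) {
  if (!length(candidates)) return(character())
  records <- records[stats::complete.cases(records[candidates]), ]
  selected <- character()
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    # forward step: best new candidate
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) {
        f <- tryCatch(cox_fit(records, c(selected, cand)),
                      error = function(e) NULL, warning = function(w) NULL)
        if (is.null(f)) return(NA_real_)
        f$p[length(f$p)]
      }, 0)
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && min(pvals) < p_enter) {
        selected <- c(selected, names(which.min(pvals)))
        changed <- TRUE
      }
    }
    # backward step: worst included covariate
    if (length(selected)) {
      f <- cox_fit(records, selected)
      # p-value per covariate = max over its model terms (factors expand)
      pv <- vapply(selected, function(cv) {
        max(f$p[grep(paste0("^", cv), names(f$p))])
      }, 0)
      if (max(pv) >= p_exit) {
        selected <- setdiff(selected, names(which.max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) return(selected)
  }
  warning("stepwise selection hit the iteration cap; possible cycling")
  selected
}

#' Quartile-versus-control hazard-ratio analysis
#'
#' For each exposure quartile of the treated arm, fits a Cox model comparing
#' that quartile's subjects with the full control arm (one model per
#' quartile), adjusted for the supplied covariates, and estimates the
#' Kaplan-Meier curve per group (four quartiles plus control).  Subjects
#' with missing adjusting covariates are omitted.
#'
#' @param treated data.frame of treated subjects with \code{time},
#'   \code{event}, a \code{quartile} factor and any adjuster columns.
#' @param control data.frame of control subjects (same outcome/adjuster
#'   columns).
#' @param adjusters character vector of adjusting covariate names (may be
#'   empty).
#' @return a list with \code{hr_table} (data.frame quartile / n_control /
#'   n_quartile / hr / lower / upper / p), \code{fits} (list of
#'   \code{cox_fit}), and \code{km} (named list of \code{km_curve}: control
#'   plus Q1-Q4).
#' @export
quartile_hr_analysis <- function(treated, control, adjusters = character()) {
  if (!nrow(control)) stop("control arm is empty")
  qlev <- levels(treated$quartile)
  km <- list(control = km_estimate(control))
  fits <- list()
  rows <- list()
  for (q in qlev) {
    sub <- treated[treated$quartile == q, , drop = FALSE]
    if (!nrow(sub)) stop("empty quartile: ", q)
    km[[q]] <- km_estimate(sub)
    dat <- rbind(
      cbind(sub[c("time", "event", adjusters)], trt = 1L),
      cbind(control[c("time", "event", adjusters)], trt = 0L))
    dat <- dat[stats::complete.cases(dat), ]
    f <- cox_fit(dat, c("trt", adjusters))
    fits[[q]] <- f
    rows[[q]] <- data.frame(quartile = q,
                            n_control = sum(dat$trt == 0),
                            n_quartile = sum(dat$trt == 1),
                            hr = f$hr[["trt"]],
                            lower = f$ci_lower[["trt"]],
                            upper = f$ci_upper[["trt"]],
                            p = f$p[["trt"]])
  }
  list(hr_table = do.call(rbind, c(rows, make.row.names = FALSE)),
       fits = fits, km = km)
}

#' Propensity (logit) scores for case-group membership
#'
#' Logistic regression of case status on the matching factors over the
#' pooled case + control records (complete cases only); returns the linear
#' predictor (logit score) for every subject and its pooled SD, which sets
#' the matching caliper.
#'
#' @param pooled data.frame containing \code{case} (logical/0-1) and the
#'   factor columns.
#' @param factors character vector of matching factor names.
#' @return list with \code{logit} (named by row of \code{pooled}),
#'   \code{sd_logit}, \code{coef}, and \code{separation}.
#' @export
propensity_logit <- function(pooled, factors) {
  for (cv in factors) {
    x <- pooled[[cv]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("constant matching factor: ", cv)
  }
  keep <- stats::complete.cases(pooled[factors])
  dat <- pooled[keep, , drop = FALSE]
  f <- stats::as.formula(paste("case ~", paste(factors, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, data = dat, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  if (separation) warning("possible separation in the propensity model")
  lp <- stats::predict(fit, type = "link")
  list(logit = lp, sd_logit = stats::sd(lp), coef = stats::coef(fit),
       separation = separation, complete = which(keep))
}

#' Mahalanobis caliper matching
#'
#' 1:1 greedy nearest-neighbour matching without replacement: cases are
#' processed in descending logit-score order (hardest to match first) and
#' each takes the unused control at minimal Mahalanobis distance over the
#' matching factors, restricted to controls whose logit score differs by at
#' most \code{caliper_mult} times the pooled logit-score SD.  Subjects with
#' missing matching factors must be excluded upstream.  A singular factor
#' covariance falls back to the Moore-Penrose pseudo-inverse with a warning.
#'
#' @param cases,controls data.frames of complete-case subjects with the
#'   factor columns (categorical factors are coerced to numeric dummies via
#'   \code{model.matrix} internally).
#' @param factors character vector of matching factor names.
#' @param caliper_mult caliper width in logit-score SDs (default 0.25).
#' @return a \code{matched_set}: list with \code{pairs} (data.frame case_id /
#'   control_id / distance / logit_gap), \code{caliper}, \code{sd_logit},
#'   \code{unmatched_cases}, and the score list.
#' @export
mahalanobis_match <- function(cases, controls, factors, caliper_mult = 0.25) {
  if (!nrow(cases) || !nrow(controls))
    stop("need at least one case and one control")
  pooled <- rbind(cbind(cases[factors], case = 1L),
                  cbind(controls[factors], case = 0L))
  if (any(!stats::complete.cases(pooled[factors])))
    stop("matching factors must be complete; exclude missing subjects upstream")
  ps <- propensity_logit(pooled, factors)
  n_ca <- nrow(cases)
  logit_ca <- ps$logit[seq_len(n_ca)]
  logit_co <- ps$logit[-seq_len(n_ca)]
  caliper <- caliper_mult * ps$sd_logit
  # numeric design over both groups for the Mahalanobis metric
  mm <- stats::model.matrix(~ . - 1, data = pooled[factors])
  S <- stats::cov(mm)
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular factor covariance; using pseudo-inverse")
    MASS::ginv(S)
  })
  X_ca <- mm[seq_len(n_ca), , drop = FALSE]
  X_co <- mm[-seq_len(n_ca), , drop = FALSE]
  used <- rep(FALSE, nrow(controls))
  pairs <- list()
  unmatched <- integer()
  for (i in order(logit_ca, decreasing = TRUE)) {
    ok <- !used & abs(logit_co - logit_ca[i]) <= caliper
    if (!any(ok)) {
      unmatched <- c(unmatched, i)
      next
    }
    d <- mahalanobis(X_co[ok, , drop = FALSE], X_ca[i, ], Sinv,
                     inverted = TRUE)
    j <- which(ok)[which.min(d)]
    used[j] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      case = i, control = j, distance = sqrt(min(d)),
      logit_gap = abs(logit_co[j] - logit_ca[i]))
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case = integer(), control = integer(), distance = numeric(),
               logit_gap = numeric())
  if ("id" %in% names(cases)) pairs$case_id <- cases$id[pairs$case]
  if ("id" %in% names(controls)) pairs$control_id <- controls$id[pairs$control]
  structure(list(pairs = pairs, caliper = caliper, sd_logit = ps$sd_logit,
                 unmatched_cases = sort(unmatched), propensity = ps),
            class = "matched_set")
}

#' @export
print.matched_set <- function(x, ...) {
  cat(sprintf("Matched set: %d pairs, %d unmatched cases, caliper %.4f (logit)\n",
              nrow(x$pairs), length(x$unmatched_cases), x$caliper))
  invisible(x)
}

#' Balance tests before and after matching
#'
#' For every matching factor, compares cases and controls with a two-sided
#' Fisher exact test (categorical/logical) or a two-sample t test
#' (continuous), both on the full groups (pre-matching) and on the matched
#' pairs (post-matching).  Single-level factors are skipped with a note.
#'
#' @param matched a \code{matched_set} from [mahalanobis_match()].
#' @param cases,controls the data.frames used for matching.
#' @param factors factor names.
#' @return data.frame with columns \code{factor}, \code{test},
#'   \code{p_pre}, \code{p_post}, \code{note}.
#' @export
balance_test <- function(matched, cases, controls, factors) {
  if (!nrow(matched$pairs)) stop("no matched pairs")
  ca_m <- cases[matched$pairs$case, , drop = FALSE]
  co_m <- controls[matched$pairs$control, , drop = FALSE]
  one <- function(x_ca, x_co) {
    if (is.numeric(x_ca) && length(unique(c(x_ca, x_co))) > 2) {
      list(test = "t", p = tryCatch(stats::t.test(x_ca, x_co)$p.value,
                                    error = function(e) NA_real_))
    } else {
      tab <- table(group = rep(c("case", "control"),
                               c(length(x_ca), length(x_co))),
                   value = c(as.character(x_ca), as.character(x_co)))
      if (ncol(tab) < 2)
        return(list(test = "skipped", p = NA_real_))
      list(test = "fisher", p = stats::fisher.test(tab)$p.value)
    }
  }
  rows <- lapply(factors, function(cv) {
    pre <- one(cases[[cv]], controls[[cv]])
    post <- one(ca_m[[cv]], co_m[[cv]])
    data.frame(factor = cv, test = pre$test, p_pre = pre$p, p_post = post$p,
               note = ifelse(pre$test == "skipped", "single level", ""))
  })
  do.call(rbind, rows)
}

#' Matched case-control analysis by exposure quartile
#'
#' Reproduces the matched sensitivity analysis: within each exposure
#' quartile, cases (that quartile's treated subjects) are matched 1:1 to
#' controls drawn from the full control arm using [mahalanobis_match()],
#' balance is tested before and after matching, and a Cox model compares the
#' matched groups.
#'
#' @param treated treated-arm data.frame with \code{quartile}, outcomes and
#'   factor columns.
#' @param control control-arm data.frame.
#' @param factors matching factor names (complete cases enforced: subjects
#'   missing any factor are excluded).
#' @param caliper_mult caliper width in logit-score SDs.
#' @return named list per quartile: \code{matched}, \code{balance},
#'   \code{cox} (a \code{cox_fit}, or NULL if fewer than 2 pairs or no
#'   events).
#' @export
matched_quartile_analysis <- function(treated, control, factors,
                                      caliper_mult = 0.25) {
  treated <- treated[stats::complete.cases(treated[factors]), , drop = FALSE]
  control <- control[stats::complete.cases(control[factors]), , drop = FALSE]
  out <- list()
  for (q in levels(treated$quartile)) {
    cases <- treated[treated$quartile == q, , drop = FALSE]
    m <- mahalanobis_match(cases, control, factors, caliper_mult)
    bal <- balance_test(m, cases, control, factors)
    dat <- rbind(cbind(cases[m$pairs$case, c("time", "event")], trt = 1L),
                 cbind(control[m$pairs$control, c("time", "event")], trt = 0L))
    cox <- if (nrow(m$pairs) >= 2 && sum(dat$event) >= 1)
      tryCatch(cox_fit(dat, "trt"), error = function(e) NULL) else NULL
    out[[q]] <- list(matched = m, balance = bal, cox = cox)
  }
  out
}
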