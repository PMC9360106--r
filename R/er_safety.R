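#' Select safety endpoints for exposure-safety analysis
#'
#' Applies the protocol's endpoint filter: Grade >= 3 treatment-emergent
#' adverse-event terms occurring in at least \code{min_treated_pct} of
#' treated subjects and with an incidence at least \code{min_diff_pct}
#' percentage points higher than in the control arm.  Configured adverse
#' events of special interest (AESI) are always carried, except that a term
#' whose any-grade rule is evaluated with less than \code{min_diff_pct}
#' between-arm difference at Grade >= 3 is annotated as not analysable at
#' that severity (the rule used to skip Grade >= 3 transaminase analyses).
#'
#' @param ae_wide data.frame with \code{id}, \code{arm} and one
#'   \code{grade_<term>} column per term (worst grade per subject).
#' @param aesi character vector of AESI terms always retained (any grade).
#' @param min_treated_pct,min_diff_pct filter thresholds in percent.
#' @return data.frame with \code{term}, \code{severity} ("grade3plus" or
#'   "any"), \code{pct_treated}, \code{pct_control}, \code{selected},
#'   \code{reason}.
#' @export
select_safety_endpoints <- function(ae_wide,
                                    aesi = c("hypertension", "proteinuria",
                                             "alt_increased", "ast_increased"),
                                    min_treated_pct = 5, min_diff_pct = 2) {
  trt <- ae_wide$arm == "RAM+ERL"
  if (!any(trt) || all(trt)) stop("both arms must be nonempty")
  terms <- sub("^grade_", "", grep("^grade_", names(ae_wide), value = TRUE))
  pct <- function(term, rule, grp) {
    g <- ae_wide[[paste0("grade_", term)]][grp]
    100 * mean(if (rule == "any") g >= 1 else g >= 3)
  }
  rows <- list()
  for (term in terms) {
    p_t3 <- pct(term, "g3", trt); p_c3 <- pct(term, "g3", !trt)
    sel3 <- p_t3 >= min_treated_pct & (p_t3 - p_c3) >= min_diff_pct
    rows[[length(rows) + 1]] <- data.frame(
      term = term, severity = "grade3plus", pct_treated = p_t3,
      pct_control = p_c3, selected = sel3,
      reason = if (sel3) "TEAE filter passed" else
        if (p_t3 < min_treated_pct) "below treated incidence threshold" else
          "between-arm difference below threshold")
    if (term %in% aesi) {
      p_ta <- pct(term, "any", trt); p_ca <- pct(term, "any", !trt)
      rows[[length(rows) + 1]] <- data.frame(
        term = term, severity = "any", pct_treated = p_ta,
        pct_control = p_ca, selected = TRUE, reason = "AESI")
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Adverse-event incidence by exposure quartile
#'
#' Counts subjects (not events) whose worst grade satisfies the severity
#' rule, by group: control arm, overall treated, and treated exposure
#' quartiles Q1-Q4.
#'
#' @param ae_wide data.frame with \code{id}, \code{arm} and
#'   \code{grade_<term>} columns.
#' @param quartiles data.frame with \code{id} and \code{quartile} (factor
#'   Q1-Q4) for every treated subject in \code{ae_wide}.
#' @param endpoints data.frame with \code{term} and \code{severity} rows to
#'   tabulate (e.g. the selected rows of [select_safety_endpoints()]).
#' @return an \code{incidence_table} data.frame: one row per term x
#'   severity, columns \code{<group>_n} and \code{<group>_pct} for control,
#'   treated, Q1-Q4, plus group sizes as an attribute.
#' @export
incidence_by_quartile <- function(ae_wide, quartiles, endpoints) {
  trt <- ae_wide[ae_wide$arm == "RAM+ERL", , drop = FALSE]
  ctl <- ae_wide[ae_wide$arm != "RAM+ERL", , drop = FALSE]
  q <- quartiles$quartile[match(trt$id, quartiles$id)]
  if (any(is.na(q)))
    stop("treated subject(s) without a quartile label: ",
         paste(utils::head(trt$id[is.na(q)]), collapse = ", "))
  groups <- c(list(control = ctl, treated = trt),
              stats::setNames(lapply(paste0("Q", 1:4), function(qq)
                trt[q == qq, , drop = FALSE]), paste0("Q", 1:4)))
  rows <- list()
  for (i in seq_len(nrow(endpoints))) {
    term <- endpoints$term[i]; sev <- endpoints$severity[i]
    row <- data.frame(term = term, severity = sev)
    for (g in names(groups)) {
      gr <- groups[[g]][[paste0("grade_", term)]]
      n <- sum(if (sev == "any") gr >= 1 else gr >= 3)
      row[[paste0(g, "_n")]] <- n
      row[[paste0(g, "_pct")]] <- 100 * n / max(nrow(groups[[g]]), 1)
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- vapply(groups, nrow, 0L)
  class(out) <- c("incidence_table", "data.frame")
  out
}

#' Format an incidence table with integer percentages
#'
#' @param x an \code{incidence_table}.
#' @return data.frame of "n (pct)" strings, percentages rounded to integers.
#' @export
format_incidence <- function(x) {
  groups <- sub("_n$", "", grep("_n$", names(x), value = TRUE))
  out <- x[c("term", "severity")]
  for (g in groups)
    out[[g]] <- sprintf("%d (%.0f)", x[[paste0(g, "_n")]],
                        x[[paste0(g, "_pct")]])
  out
}

#' Proportional-odds model of grade versus exposure
#'
#' Cumulative-logit (proportional-odds) regression of the ordinal worst
#' grade on an exposure measure, fit by maximum likelihood.  The model is
#' parameterised as \code{logit P(grade >= k) = alpha_k + beta * exposure},
#' so a positive \code{beta} means higher exposure shifts subjects into
#' worse categories.  Grades are grouped into 0 / 1-2 / >= 3 by default;
#' the full 0-5 scale is available via \code{collapse = FALSE}.  Empty
#' categories are collapsed with a warning; when only two categories remain
#' the fit degenerates to ordinary logistic regression.
#'
#' @param grades integer worst grades (0-5).
#' @param exposure exposure values, ug/mL, same length.
#' @param collapse group grades into 0 / 1-2 / >= 3 (default TRUE).
#' @return a \code{prop_odds_fit}: list with \code{alpha} (cutpoint
#'   intercepts, increasing severity order), \code{beta}, \code{se_beta},
#'   \code{p} (Wald test on beta), \code{loglik}, \code{n_categories}.
#' @export
proportional_odds_fit <- function(grades, exposure, collapse = TRUE) {
  stopifnot(length(grades) == length(exposure))
  if (any(grades < 0 | grades > 5 | grades != round(grades)))
    stop("grades must be integers in 0-5")
  cat_lab <- if (collapse)
    cut(grades, c(-1, 0, 2, 5), labels = c("0", "1-2", ">=3")) else
      factor(grades, levels = 0:5)
  present <- levels(droplevels(cat_lab))
  if (length(present) < length(levels(cat_lab))) {
    warning("empty grade categories collapsed")
    cat_lab <- droplevels(cat_lab)
  }
  k <- nlevels(cat_lab)
  if (k < 2) stop("grades are constant; no model to fit")
  if (k == 2) {
    y <- as.integer(cat_lab == levels(cat_lab)[2])
    fit <- stats::glm(y ~ exposure, family = stats::binomial())
    beta <- stats::coef(fit)[["exposure"]]
    se <- sqrt(diag(stats::vcov(fit)))[["exposure"]]
    if (abs(beta) > 5) warning("possible separation in the two-category fit")
    return(structure(list(alpha = unname(stats::coef(fit)[1]), beta = beta,
                          se_beta = se,
                          p = 2 * stats::pnorm(-abs(beta / se)),
                          loglik = as.numeric(stats::logLik(fit)),
                          n_categories = 2L),
                     class = "prop_odds_fit"))
  }
  # polr models logit P(Y <= k) = zeta_k - eta; with eta = b * exposure this
  # is logit P(Y >= k+1) = -zeta_k + b * exposure, so alpha = -zeta, beta = b
  fit <- MASS::polr(cat_lab ~ exposure, Hess = TRUE)
  beta <- stats::coef(fit)[["exposure"]]
  se <- sqrt(diag(stats::vcov(fit)))[["exposure"]]
  if (abs(beta) > 5) warning("possible separation in the ordinal fit")
  structure(list(alpha = unname(-fit$zeta), beta = beta, se_beta = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = as.numeric(stats::logLik(fit)),
                 n_categories = k),
            class = "prop_odds_fit")
}

#' @export
print.prop_odds_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit (%d categories): beta %.4g per ug/mL (p = %.3g)\n",
              x$n_categories, x$beta, x$p))
  invisible(x)
}

#' Relative dose intensity and dose-adjustment summary
#'
#' Per-subject relative dose intensity (RDI): received cumulative dose as a
#' percentage of the protocol-planned cumulative dose over the subject's
#' actual treatment duration, together with an indicator of any dose
#' adjustment (delay beyond \code{delay_tol_h}, reduction below the starting
#' mg/kg, or omission).  Summaries are returned per exposure quartile.
#'
#' @param doses named list (by subject id) of \code{dose_events} with actual
#'   \code{start}, \code{amount}, \code{dose_per_kg}; zero-amount rows are
#'   omissions.
#' @param quartiles data.frame with \code{id} and \code{quartile} for the
#'   subjects to summarise.
#' @param reg the planned [regimen()].
#' @param weights named vector (by subject id) of body weights, kg.
#' @param delay_tol_h slack before a shifted dose counts as delayed
#'   (default 24 h).
#' @return list with \code{per_subject} (id, quartile, rdi_pct, adjusted)
#'   and \code{by_quartile} (quartile, n, mean_rdi_pct, pct_adjusted).
#' @export
dose_intensity_summary <- function(doses, quartiles, reg, weights,
                                   delay_tol_h = 24) {
  rows <- lapply(seq_len(nrow(quartiles)), function(i) {
    id <- as.character(quartiles$id[i])
    ev <- doses[[id]]
    if (is.null(ev)) stop("no dosing history for subject ", id)
    w <- weights[[id]]
    n_given <- nrow(ev)
    planned_start <- (seq_len(n_given) - 1) * reg$interval
    planned <- reg$dose_per_kg * w * n_given
    if (planned <= 0) stop("zero planned dose for subject ", id)
    received <- sum(ev$amount)
    dpk <- if (!is.null(ev$dose_per_kg)) ev$dose_per_kg else ev$amount / w
    adjusted <- any(ev$amount == 0) ||
      any(dpk < reg$dose_per_kg - 1e-9 & ev$amount > 0) ||
      any(ev$start - planned_start > delay_tol_h)
    data.frame(id = quartiles$id[i], quartile = quartiles$quartile[i],
               rdi_pct = 100 * received / planned, adjusted = adjusted)
  })
  per_subject <- do.call(rbind, rows)
  by_quartile <- do.call(rbind, lapply(split(per_subject,
                                             per_subject$quartile,
                                             drop = TRUE),
                                       function(d) data.frame(
    quartile = d$quartile[1], n = nrow(d),
    mean_rdi_pct = mean(d$rdi_pct),
    pct_adjusted = 100 * mean(d$adjusted))))
  rownames(by_quartile) <- NULL
  list(per_subject = per_subject, by_quartile = by_quartile)
}
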