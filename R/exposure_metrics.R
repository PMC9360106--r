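#' Assign exposure quartiles
#'
#' Splits positive exposure values into four groups by rank: Q1 (< 25%),
#' Q2 (25-<50%), Q3 (50-<75%), Q4 (>= 75%).  The split is rank-based with a
#' stable order (ties broken by the supplied \code{ids}, i.e. input order by
#' default), boundary values going to the lower group, so group sizes differ
#' by at most one; with \code{n = 4k} each group has exactly \code{k}
#' members.  Edges are reported as the (min, max) of each group.
#'
#' @param values positive exposures, ug/mL (n >= 4).
#' @param ids optional subject ids used for stable tie-breaking and row
#'   labels.
#' @return a list with \code{labels} (factor Q1-Q4 aligned with
#'   \code{values}) and \code{edges} (data.frame quartile/n/min/max).
#' @export
assign_quartiles <- function(values, ids = seq_along(values)) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values to form quartiles")
  if (any(!is.finite(values) | values <= 0))
    stop("exposures must be positive and finite")
  ord <- order(values, ids)
  # ranks 0..n-1 in stable value order; boundaries at 25/50/75% of n,
  # boundary ranks fall in the lower group
  cuts <- ceiling(n * c(1, 2, 3) / 4)
  grp <- integer(n)
  grp[ord] <- findInterval(seq_len(n), cuts + 1L) + 1L
  labels <- factor(paste0("Q", grp), levels = paste0("Q", 1:4))
  edges <- do.call(rbind, lapply(1:4, function(q) {
    v <- values[grp == q]
    data.frame(quartile = paste0("Q", q), n = length(v),
               min = min(v), max = max(v))
  }))
  list(labels = labels, edges = edges)
}

#' Summarise an exposure distribution
#'
#' Geometric mean (\code{exp(mean(log x))}), natural-scale CV%
#' (\code{100 * sd/mean}), selected low percentiles and the range, matching
#' the layout used for steady-state trough reporting.  Percentiles use
#' linear interpolation of the empirical CDF (type 7).
#'
#' @param values positive exposures, ug/mL.
#' @param probs percentile levels to report.
#' @return data.frame with one row: \code{n}, \code{geomean}, \code{cv_pct},
#'   \code{p5}, \code{p10}, \code{p20} (per \code{probs}), \code{min},
#'   \code{max}.
#' @export
summarize_exposure <- function(values, probs = c(0.05, 0.10, 0.20)) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop("nonpositive exposure for subject(s) ", paste(bad, collapse = ", "))
  qs <- stats::quantile(values, probs, type = 7, names = FALSE)
  out <- data.frame(n = length(values),
                    geomean = exp(mean(log(values))),
                    cv_pct = 100 * stats::sd(values) / mean(values))
  for (i in seq_along(probs))
    out[[paste0("p", round(100 * probs[i]))]] <- qs[i]
  out$min <- min(values)
  out$max <- max(values)
  out
}

#' Fraction of exposures above a threshold
#'
#' @param values exposures, ug/mL (nonempty).
#' @param threshold target concentration, ug/mL.
#' @return proportion of values strictly above the threshold.
#' @export
fraction_above <- function(values, threshold) {
  if (!length(values)) stop("empty exposure vector")
  mean(values > threshold)
}

#' Build exposure records for the treated cohort
#'
#' Combines per-subject Cmin,1 and Cmin,ss with their cohort quartile
#' labels.
#'
#' @param exposures data.frame with \code{id}, \code{cmin1}, \code{cminss}.
#' @return data.frame with added factor columns \code{quartile_cmin1} and
#'   \code{quartile_cminss}, plus \code{edges_cmin1}/\code{edges_cminss}
#'   attributes.
#' @export
exposure_records <- function(exposures) {
  q1 <- assign_quartiles(exposures$cmin1, exposures$id)
  qs <- assign_quartiles(exposures$cminss, exposures$id)
  exposures$quartile_cmin1 <- q1$labels
  exposures$quartile_cminss <- qs$labels
  attr(exposures, "edges_cmin1") <- q1$edges
  attr(exposures, "edges_cminss") <- qs$edges
  exposures
}
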