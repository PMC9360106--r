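#' Write a NONMEM-style longitudinal PK dataset
#'
#' Serialises dosing and observation records to the conventional
#' nonlinear-mixed-effects CSV layout: one row per event with columns
#' \code{ID}, \code{TIME} (h), \code{AMT} (mg; dose rows), \code{RATE}
#' (mg/h), \code{DUR} (h), \code{DV} (ug/mL; observation rows), \code{EVID}
#' (1 = dose, 0 = observation) and \code{WT} (kg).
#'
#' @param doses named list (by subject id) of \code{dose_events}.
#' @param observations named list (by subject id) of observation
#'   \code{concentration_profile}s (may omit subjects).
#' @param weights named vector (by subject id) of body weights, kg.
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
write_nonmem <- function(doses, observations, weights, path) {
  rows <- list()
  for (id in names(doses)) {
    ev <- doses[[id]]
    w <- weights[[id]]
    rows[[length(rows) + 1]] <- data.frame(
      ID = id, TIME = ev$start, AMT = ev$amount,
      RATE = ifelse(ev$duration > 0, ev$amount / ev$duration, 0),
      DUR = ev$duration, DV = NA_real_, EVID = 1L, WT = w)
    obs <- observations[[id]]
    if (!is.null(obs))
      rows[[length(rows) + 1]] <- data.frame(
        ID = id, TIME = obs$times, AMT = NA_real_, RATE = NA_real_,
        DUR = NA_real_, DV = obs$values, EVID = 0L, WT = w)
  }
  out <- do.call(rbind, rows)
  out <- out[order(as.numeric(out$ID), out$TIME, -out$EVID), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}

#' Read a NONMEM-style longitudinal PK dataset
#'
#' Parses the CSV layout written by [write_nonmem()] (accepting either
#' \code{RATE} or \code{DUR} for the infusion length) back into per-subject
#' dose events and observation profiles.
#'
#' @param path CSV path with columns ID, TIME, AMT, RATE and/or DUR, DV,
#'   EVID, and optionally WT.
#' @return list with \code{doses} (named list of \code{dose_events}),
#'   \code{observations} (named list of \code{concentration_profile}) and
#'   \code{weights} (named numeric).
#' @export
read_nonmem <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- toupper(names(d))
  need <- c("ID", "TIME", "EVID")
  if (!all(need %in% names(d)))
    stop("missing required columns: ", paste(setdiff(need, names(d)),
                                             collapse = ", "))
  doses <- list()
  observations <- list()
  weights <- numeric()
  for (id in unique(d$ID)) {
    sub <- d[d$ID == id, , drop = FALSE]
    dos <- sub[sub$EVID == 1, , drop = FALSE]
    dur <- if ("DUR" %in% names(dos) && any(is.finite(dos$DUR))) dos$DUR
      else dos$AMT / dos$RATE
    ev <- data.frame(start = dos$TIME, amount = dos$AMT, duration = dur)
    class(ev) <- c("dose_events", "data.frame")
    doses[[as.character(id)]] <- ev
    obs <- sub[sub$EVID == 0, , drop = FALSE]
    if (nrow(obs))
      observations[[as.character(id)]] <- structure(
        list(times = obs$TIME, values = obs$DV, kind = "observation"),
        class = "concentration_profile")
    if ("WT" %in% names(sub))
      weights[[as.character(id)]] <- sub$WT[1]
  }
  list(doses = doses, observations = observations, weights = weights)
}
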