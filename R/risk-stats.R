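#' Annotate seizures with the sleep-wake state at onset
#'
#' The state at onset is the label of the 30-s epoch containing the onset.
#' For the sleep/wake dichotomy, brief arousals inside a sleep period
#' (WASO) count as sleep; seizures landing in UNKNOWN epochs are flagged
#' and excluded from state statistics.
#'
#' @param seizures data.frame with POSIXct `onset` (and any other columns,
#'   carried through).
#' @param h a [hypnogram()].
#' @param periods optional [detect_sleep_periods()] output used to decide
#'   whether a WAKE onset lies inside a sleep period (WASO).
#' @return `seizures` with added columns `state` (epoch label), `waso`
#'   (logical: wake onset inside a sleep period) and `during_sleep`
#'   (logical; NA for UNKNOWN states).
#' @export
annotate_seizure_states <- function(seizures, h, periods = NULL) {
  t0 <- h$timestamp[1]
  t1 <- h$timestamp[nrow(h)] + EPOCH_SEC
  if (any(seizures$onset < t0 | seizures$onset >= t1))
    stop("seizure onset outside the hypnogram span")
  idx <- floor(as.numeric(seizures$onset - t0, units = "secs") / EPOCH_SEC) + 1
  state <- as.character(h$label)[idx]
  waso <- rep(FALSE, nrow(seizures))
  if (!is.null(periods) && nrow(periods)) {
    for (j in which(state == "WAKE")) {
      waso[j] <- any(seizures$onset[j] >= periods$onset &
                       seizures$onset[j] < periods$offset)
    }
  }
  during_sleep <- state %in% SLEEP_STAGES | waso
  during_sleep[state == "UNKNOWN"] <- NA
  seizures$state <- state
  seizures$waso <- waso
  seizures$during_sleep <- during_sleep
  seizures
}

#' Per-state seizure rate and duration
#'
#' Rate in state s is the number of seizures with onset in s divided by the
#' hours recorded in s. States with zero recorded time are omitted with a
#' warning.
#'
#' @param seizures output of [annotate_seizure_states()].
#' @param h the matching [hypnogram()].
#' @param states states to tabulate.
#' @return data.frame with `state`, `hours`, `n_seizures`, `rate_per_h`,
#'   `mean_duration_min`.
#' @export
seizure_rate_duration_by_state <- function(seizures, h,
                                           states = STAGE_LEVELS[1:5]) {
  lab <- as.character(h$label)
  rows <- lapply(states, function(s) {
    hours <- sum(lab == s) * EPOCH_SEC / 3600
    if (hours == 0) {
      warning("no recorded time in state ", s, "; omitted")
      return(NULL)
    }
    sel <- seizures$state == s
    data.frame(state = s, hours = hours, n_seizures = sum(sel),
               rate_per_h = sum(sel) / hours,
               mean_duration_min = if (any(sel))
                 mean(seizures$duration_s[sel]) / 60 else NA_real_)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Categorize days by a sleep variable's interquartile range
#'
#' Per patient, the 25th and 75th percentiles of the variable are computed
#' on seizure-free days only (linear interpolation between order
#' statistics). Values below the 25th percentile are `decreased`, above the
#' 75th `increased`, and baseline includes both endpoints. Seizure days are
#' labelled `excluded` and never shift the thresholds.
#'
#' @param days data.frame with one row per day: a `patient` column, the
#'   variable column, and a 0/1 `seizure_day` column.
#' @param variable name of the sleep variable column (e.g.
#'   `"total_sleep_h"` or `"rem_prop"`).
#' @param min_days minimum seizure-free days per patient (default 8);
#'   patients below it are skipped with a warning.
#' @return `days` with added `category` column (factor baseline / decreased
#'   / increased / excluded; NA for skipped patients) and the per-patient
#'   thresholds as the `thresholds` attribute.
#' @export
categorize_days <- function(days, variable, min_days = 8) {
  stopifnot(variable %in% names(days), "seizure_day" %in% names(days))
  category <- rep(NA_character_, nrow(days))
  th <- list()
  for (p in unique(days$patient)) {
    sel <- days$patient == p
    v <- days[[variable]][sel]
    free <- days$seizure_day[sel] == 0 & !is.na(v)
    if (sum(free) < min_days) {
      warning("patient ", p, " has fewer than ", min_days,
              " seizure-free days; skipped")
      next
    }
    q <- stats::quantile(v[free], c(0.25, 0.75), names = FALSE)
    cat_p <- ifelse(v < q[1], "decreased",
                    ifelse(v > q[2], "increased", "baseline"))
    cat_p[days$seizure_day[sel] == 1] <- "excluded"
    cat_p[is.na(v)] <- NA
    category[sel] <- cat_p
    th[[as.character(p)]] <- data.frame(patient = p, p25 = q[1], p75 = q[2])
  }
  days$category <- factor(category,
                          levels = c("baseline", "decreased", "increased",
                                     "excluded"))
  attr(days, "thresholds") <- do.call(rbind, th)
  days
}

#' Binary 48-hour seizure outcome per categorized day
#'
#' The outcome is 1 if at least one seizure onset falls in the 48 hours
#' after the end of the day's 24-h measurement window — the half-open
#' interval `(window_end, window_end + 48 h]`.
#'
#' @param days data.frame with `patient` and `day` (Date key, see
#'   [day_key()]) columns.
#' @param seizures data.frame with `patient` and POSIXct `onset`.
#' @param window_h outcome window length in hours (default 48).
#' @return `days` with an added 0/1 `outcome` column.
#' @export
outcome_within_48h <- function(days, seizures, window_h = 48) {
  ends <- day_window_end(days$day)
  days$outcome <- vapply(seq_len(nrow(days)), function(i) {
    sel <- seizures$patient == days$patient[i]
    as.integer(any(seizures$onset[sel] > ends[i] &
                     seizures$onset[sel] <= ends[i] + window_h * 3600))
  }, 0L)
  days
}

#' Classify days as control / wake-seizure / sleep-seizure
#'
#' Seizure-free days are controls; days whose seizures all occurred while
#' awake are `wake_sz`; days whose seizures all occurred during sleep
#' (including WASO arousals) are `sleep_sz`; days with both kinds are
#' excluded.
#'
#' @param days data.frame with `patient` and `day` (Date) columns.
#' @param seizures output of [annotate_seizure_states()], with a `patient`
#'   column.
#' @return `days` with an added `postseizure_class` factor.
#' @export
classify_postseizure_days <- function(days, seizures) {
  key <- paste(days$patient, days$day)
  skey <- paste(seizures$patient, day_key(seizures$onset))
  cls <- vapply(seq_len(nrow(days)), function(i) {
    sl <- seizures$during_sleep[skey == key[i]]
    sl <- sl[!is.na(sl)]
    if (!length(sl)) "control"
    else if (all(sl)) "sleep_sz"
    else if (!any(sl)) "wake_sz"
    else "excluded"
  }, "")
  days$postseizure_class <- factor(cls, levels = c("control", "wake_sz",
                                                   "sleep_sz", "excluded"))
  days
}
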