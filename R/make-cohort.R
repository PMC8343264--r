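#' Simulate a multi-patient cohort with known ground truth
#'
#' Builds a cohort of patients at one of two fidelity levels.
#'
#' `level = "day"` (fast path) simulates day-level records only: planned
#' nightly sleep durations, interquartile categorization, seizure days from
#' the random-intercept logistic generating model, and post-seizure
#' feedback (a seizure lengthens the next day's sleep; a sleep seizure also
#' raises WASO and lowers REM the next night).
#'
#' `level = "hypnogram"` additionally realizes a full 30-s epoch hypnogram
#' per patient whose nightly durations and post-seizure shifts match the
#' day-level simulation, places seizure events into real epochs, and
#' carries dropout/artifact masks. Raw signals can then be synthesized on
#' demand with [generate_signal()].
#'
#' @param n_patients number of patients (>= 1).
#' @param n_days either a single day count for all patients, a vector (one
#'   per patient), or `NULL` to draw uniformly from `days_range`.
#' @param days_range range from which per-patient day counts are drawn when
#'   `n_days` is NULL (default 224-709, the scale of long-term ambulatory
#'   monitoring cohorts).
#' @param sleep a [sleep_params()] (shared across patients).
#' @param risk a [seizure_risk_params()].
#' @param seed RNG seed.
#' @param level `"day"` or `"hypnogram"`.
#' @param out_dir optional directory; when given, per-patient hypnogram and
#'   seizure CSVs are written there.
#' @return object of class `cohort`: a list with `patients` (named list;
#'   each entry holds `day_truth`, `events`, `intercept`, and for
#'   hypnogram-level cohorts `synth` — the [generate_hypnogram()] output),
#'   plus `params` and `level`.
#' @export
make_cohort <- function(n_patients, n_days = NULL,
                        days_range = c(224, 709),
                        sleep = sleep_params(),
                        risk = seizure_risk_params(),
                        seed = NULL, level = c("day", "hypnogram"),
                        out_dir = NULL) {
  stopifnot(n_patients >= 1)
  level <- match.arg(level)
  if (is.null(n_days)) {
    n_days <- with_seed(child_seed(seed, 90), {
      sample(days_range[1]:days_range[2], n_patients, replace = TRUE)
    })
  }
  n_days <- rep_len(n_days, n_patients)

  patients <- list()
  for (i in seq_len(n_patients)) {
    pid <- paste0("P", i)
    pseed <- child_seed(seed, 100 + i)
    patients[[pid]] <- simulate_patient(pid, n_days[i], sleep, risk,
                                        pseed, level)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(patients)) {
      p <- patients[[pid]]
      if (!is.null(p$synth))
        write_hypnogram(p$synth$hypnogram,
                        file.path(out_dir, paste0(pid, "_hypnogram.csv")))
      write_seizures(p$events,
                     file.path(out_dir, paste0(pid, "_seizures.csv")))
      utils::write.csv(p$day_truth,
                       file.path(out_dir, paste0(pid, "_days.csv")),
                       row.names = FALSE)
    }
  }
  structure(list(patients = patients, level = level,
                 sleep = sleep, risk = risk, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nd <- vapply(x$patients, function(p) nrow(p$day_truth), 0)
  nsz <- vapply(x$patients, function(p) nrow(p$events), 0)
  cat(sprintf("Synthetic cohort: %d patients, %d total days (%s level)\n",
              length(x$patients), sum(nd), x$level))
  cat("  days/patient:", paste(range(nd), collapse = "-"),
      " seizures/patient:", paste(range(nsz), collapse = "-"), "\n")
  invisible(x)
}

# One patient: day-level simulation with post-seizure feedback, optionally
# realized as an epoch-level hypnogram.
simulate_patient <- function(pid, nd, sleep, risk, seed, level) {
  with_seed(seed, {
    planned <- stats::rnorm(nd, sleep$night_sleep_duration_mean,
                            sleep$night_sleep_duration_sd)
    planned <- pmin(pmax(planned, 3), 14)
    q <- stats::quantile(planned, c(0.25, 0.75), names = FALSE)
    b0 <- stats::rnorm(1, risk$baseline_log_odds, risk$random_intercept_sd)

    w <- risk$state_placement_weights
    p_sleep_state <- sum(w[c("N1", "N2", "N3", "REM")]) / sum(w)

    adj <- planned
    category <- character(nd)
    sz <- integer(nd)
    sz_type <- rep("none", nd)
    waso_shift <- rem_shift <- numeric(nd)
    for (d in seq_len(nd)) {
      if (d > 1 && sz[d - 1] == 1) {
        eff <- risk$postseizure_effects[[
          if (sz_type[d - 1] == "sleep") "sleep_sz" else "wake_sz"]]
        adj[d] <- min(adj[d] + eff$duration_h, 14)
        waso_shift[d] <- eff$waso
        rem_shift[d] <- eff$rem
      }
      category[d] <- if (adj[d] < q[1]) "decreased"
                     else if (adj[d] > q[2]) "increased" else "baseline"
      eta <- b0 + log(risk$or_decreased) * (category[d] == "decreased") +
        log(risk$or_increased) * (category[d] == "increased")
      sz[d] <- stats::rbinom(1, 1, stats::plogis(eta))
      if (sz[d] == 1)
        sz_type[d] <- if (stats::runif(1) < p_sleep_state) "sleep" else "wake"
    }

    day_truth <- data.frame(
      patient = pid, day = seq_len(nd),
      planned_duration_h = planned, duration_h = adj,
      category = factor(category,
                        levels = c("baseline", "decreased", "increased")),
      seizure_day = sz, seizure_type = sz_type)

    synth <- NULL
    if (level == "hypnogram") {
      ov <- data.frame(day = seq_len(nd), duration_h = adj,
                       waso_shift = waso_shift, rem_shift = rem_shift)
      synth <- generate_hypnogram(sleep, nd, seed = child_seed(seed, 7),
                                  overrides = ov)
    }

    gs <- generate_seizures_from_truth(day_truth, risk,
                                       seed = child_seed(seed, 8),
                                       synth = synth)
    list(day_truth = day_truth, events = gs, intercept = b0, synth = synth)
  })
}

# Place one event per seizure day (states constrained to the realized
# hypnogram when available, honouring the day's wake/sleep seizure type).
generate_seizures_from_truth <- function(day_truth, risk, seed, synth = NULL) {
  with_seed(seed, {
    w <- risk$state_placement_weights
    m <- log(risk$seizure_duration_mean_s^2 /
               sqrt(risk$seizure_duration_mean_s^2 + risk$seizure_duration_sd_s^2))
    s <- sqrt(log(1 + risk$seizure_duration_sd_s^2 / risk$seizure_duration_mean_s^2))
    start <- if (!is.null(synth)) day_key(synth$hypnogram$timestamp[1])
             else as.Date("2020-01-01")
    rows <- lapply(which(day_truth$seizure_day == 1), function(d0) {
      d <- day_truth$day[d0]
      type <- day_truth$seizure_type[d0]
      states <- if (type == "sleep") c("N1", "N2", "N3", "REM") else "WAKE"
      ww <- w[states]
      state <- if (length(states) == 1) states else
        sample(states, 1, prob = ww / sum(ww))
      onset <- NULL
      if (!is.null(synth)) {
        h <- synth$hypnogram
        dsel <- day_key(h$timestamp) == (start + d - 1)
        cand <- which(dsel & as.character(h$label) == state)
        if (!length(cand) && type == "sleep")
          cand <- which(dsel & as.character(h$label) %in% states)
        if (length(cand))
          onset <- h$timestamp[sample(cand, 1)] + stats::runif(1, 0, EPOCH_SEC)
      }
      if (is.null(onset))
        onset <- as.POSIXct(paste(start + d - 1, "12:00:00"), tz = "UTC") +
          stats::runif(1, 0, 24 * 3600)
      data.frame(patient = day_truth$patient[d0], day = d, onset = onset,
                 duration_s = stats::rlnorm(1, m, s), state = state)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(patient = character(), day = integer(),
                 onset = as.POSIXct(character(), tz = "UTC"),
                 duration_s = numeric(), state = character())
  })
}
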