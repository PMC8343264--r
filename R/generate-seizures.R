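#' Simulate categorized day records
#'
#' Draws day-level sleep-category labels (decreased / baseline / increased)
#' with the marginal frequencies implied by interquartile categorization
#' (25% / 50% / 25% by default). This is the fast, day-level entry point for
#' studying the seizure-risk model in isolation.
#'
#' @param n_patients,n_days cohort dimensions.
#' @param probs category probabilities (decreased, baseline, increased).
#' @param seed RNG seed.
#' @return data.frame with `patient` (factor), `day` (1-based index) and
#'   `category` (factor with baseline as reference level).
#' @export
simulate_category_days <- function(n_patients, n_days,
                                   probs = c(0.25, 0.5, 0.25), seed = NULL) {
  stopifnot(length(probs) == 3, all(probs >= 0), sum(probs) > 0)
  with_seed(seed, {
    data.frame(
      patient = factor(rep(paste0("P", seq_len(n_patients)), each = n_days)),
      day = rep(seq_len(n_days), n_patients),
      category = factor(sample(c("decreased", "baseline", "increased"),
                               n_patients * n_days, replace = TRUE,
                               prob = probs / sum(probs)),
                        levels = c("baseline", "decreased", "increased")))
  })
}

#' Generate seizure days and events from categorized day records
#'
#' Day-level seizure indicators follow the generating model
#' `logit(p) = b0_i + log(or_decreased) I(dec) + log(or_increased) I(inc)`
#' with patient intercepts `b0_i ~ N(baseline_log_odds,
#' random_intercept_sd^2)`. On seizure days one event is placed: its
#' sleep-wake state at onset is drawn from `state_placement_weights` (when a
#' hypnogram is supplied the onset is an actual epoch of that state on that
#' day), and its duration is lognormal and strictly positive.
#'
#' @param day_truth data.frame with columns `patient`, `day` and `category`
#'   (levels baseline/decreased/increased); e.g. from
#'   [simulate_category_days()] or a cohort's ground truth.
#' @param params a [seizure_risk_params()].
#' @param seed RNG seed.
#' @param hypnograms optional named list (by patient) of [hypnogram()]s used
#'   to place onset times in real epochs.
#' @param start first day's date (used to stamp onset times when no
#'   hypnogram is given).
#' @return list with `seizure_day` (0/1 vector aligned to `day_truth`
#'   rows), `intercepts` (per-patient b0) and `events` (data.frame
#'   `patient`, `day`, `onset`, `duration_s`, `state`).
#' @export
generate_seizures <- function(day_truth, params, seed = NULL,
                              hypnograms = NULL,
                              start = as.Date("2020-01-01")) {
  if (nrow(day_truth) == 0 || !"category" %in% names(day_truth))
    stop("no categorized days supplied")
  stopifnot(inherits(params, "seizure_risk_params"))
  with_seed(seed, {
    pid <- factor(day_truth$patient)
    b0 <- stats::rnorm(nlevels(pid), params$baseline_log_odds,
                       params$random_intercept_sd)
    names(b0) <- levels(pid)
    eta <- b0[as.integer(pid)] +
      log(params$or_decreased) * (day_truth$category == "decreased") +
      log(params$or_increased) * (day_truth$category == "increased")
    sz <- stats::rbinom(nrow(day_truth), 1, stats::plogis(eta))

    w <- params$state_placement_weights
    m <- log(params$seizure_duration_mean_s^2 /
               sqrt(params$seizure_duration_mean_s^2 +
                      params$seizure_duration_sd_s^2))
    s <- sqrt(log(1 + params$seizure_duration_sd_s^2 /
                    params$seizure_duration_mean_s^2))
    ev <- lapply(which(sz == 1), function(i) {
      p <- as.character(pid[i]); d <- day_truth$day[i]
      state <- sample(names(w), 1, prob = w)
      onset <- NULL
      if (!is.null(hypnograms) && p %in% names(hypnograms)) {
        h <- hypnograms[[p]]
        dsel <- day_key(h$timestamp) == (start + d - 1)
        cand <- which(dsel & as.character(h$label) == state)
        if (!length(cand)) {
          present <- intersect(names(w)[w > 0],
                               unique(as.character(h$label)[dsel]))
          if (length(present)) {
            state <- sample(present, 1, prob = w[present] / sum(w[present]))
            cand <- which(dsel & as.character(h$label) == state)
          }
        }
        if (length(cand))
          onset <- h$timestamp[sample(cand, 1)] +
            stats::runif(1, 0, EPOCH_SEC)
      }
      if (is.null(onset))
        onset <- as.POSIXct(paste(start + d - 1, "12:00:00"), tz = "UTC") +
          stats::runif(1, 0, 24 * 3600)
      data.frame(patient = p, day = d, onset = onset,
                 duration_s = stats::rlnorm(1, m, s), state = state)
    })
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(patient = character(), day = integer(),
                 onset = as.POSIXct(character(), tz = "UTC"),
                 duration_s = numeric(), state = character())
    list(seizure_day = sz, intercepts = b0, events = events)
  })
}
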