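#' Simulate a multi-day hypnogram with known ground truth
#'
#' Builds an epoch-level (30 s) stage-label series covering `n_days`
#' noon-to-noon days. Each night is assembled from a short NREM lead-in
#' followed by `n_cycles` sleep cycles; every cycle starts with its REM
#' period and continues through NREM, so the recovered cycle segmentation
#' (REM start to next REM start) coincides with the generating cycles.
#' Cycle durations shrink multiplicatively across the night while the REM
#' share grows and the N3 share falls, mirroring healthy sleep architecture.
#' Brief arousals (WASO) are sprinkled inside the sleep period, daytime naps
#' are added, and recording dropouts / artifact flags are drawn per epoch.
#'
#' @param params a [sleep_params()] object.
#' @param n_days number of 24-h days to simulate (>= 1).
#' @param seed integer seed; identical seed and parameters reproduce the
#'   output exactly.
#' @param start first timestamp (noon UTC); defaults to 2020-01-01 12:00.
#' @param overrides optional data.frame with column `day` (1-based) and any
#'   of `duration_h` (absolute night duration), `duration_shift_h`,
#'   `waso_shift`, `rem_shift`, `dropout_rate`, applied to that day's night
#'   (used for post-seizure feedback and scripted scenarios).
#' @return An object of class `synthetic_hypnogram`: a list with
#'   `$hypnogram` (ground-truth labels, no UNKNOWN), `$artifact` (logical
#'   per epoch), `$missing_frac` (numeric per epoch, fraction of samples
#'   missing), `$periods` (true sleep periods: onset, offset, kind),
#'   `$cycles` (true cycle boundaries per night) and `$params`.
#' @export
generate_hypnogram <- function(params, n_days, seed = NULL,
                               start = as.POSIXct("2020-01-01 12:00:00", tz = "UTC"),
                               overrides = NULL) {
  stopifnot(inherits(params, "sleep_params"), n_days >= 1)
  validate_sleep_params(params)
  with_seed(seed, {
    n_ep <- n_days * EPOCHS_PER_DAY
    labels <- rep("WAKE", n_ep)
    timestamp <- start + EPOCH_SEC * (seq_len(n_ep) - 1)

    ov <- function(day, field, default = 0) {
      if (is.null(overrides) || !field %in% names(overrides)) return(default)
      v <- overrides[[field]][match(day, overrides$day)]
      if (is.na(v)) default else v
    }

    periods <- list(); cycles <- list()
    for (d in seq_len(n_days)) {
      # --- main night sleep -------------------------------------------------
      onset_clock <- params$mean_sleep_onset_clock_time +
        stats::rnorm(1, 0, params$onset_jitter_sd)
      onset_h_from_noon <- (onset_clock - 12) %% 24
      base_dur <- ov(d, "duration_h", NA_real_)
      if (!is.finite(base_dur))
        base_dur <- stats::rnorm(1, params$night_sleep_duration_mean,
                                 params$night_sleep_duration_sd)
      else
        stats::rnorm(1)  # keep the RNG stream aligned across override modes
      dur_h <- base_dur + ov(d, "duration_shift_h")
      dur_h <- min(max(dur_h, 3), 14)
      onset_idx <- (d - 1) * EPOCHS_PER_DAY + round(onset_h_from_noon * 120) + 1
      night <- build_night(params, dur_h,
                           waso = min(max(params$waso_fraction + ov(d, "waso_shift"), 0), 0.5),
                           rem_shift = ov(d, "rem_shift"))
      idx <- onset_idx + seq_along(night$labels) - 1
      keep <- idx <= n_ep
      if (!any(keep)) next
      labels[idx[keep]] <- night$labels[keep]
      off_idx <- max(idx[keep])
      periods[[length(periods) + 1]] <- data.frame(
        onset = timestamp[onset_idx], offset = timestamp[off_idx] + EPOCH_SEC,
        kind = if ((off_idx - onset_idx + 1) * EPOCH_SEC / 3600 < 2) "nap" else "main",
        day = d)
      cyc_keep <- night$cycle_start[night$cycle_start + onset_idx - 1 <= n_ep]
      if (length(cyc_keep) >= 1) {
        cs <- timestamp[onset_idx + cyc_keep - 1]
        ce <- c(cs[-1], timestamp[off_idx] + EPOCH_SEC)
        cycles[[length(cycles) + 1]] <- data.frame(
          night = d, index = seq_along(cs), start = cs, end = ce)
      }

      # --- naps -------------------------------------------------------------
      n_naps <- stats::rpois(1, params$nap_rate_per_day)
      for (k in seq_len(n_naps)) {
        nap_dur <- stats::runif(1, params$nap_duration_range[1],
                                params$nap_duration_range[2])
        nap_start_h <- stats::runif(1, 1, 6)  # 13:00-18:00, hours past noon
        nidx <- (d - 1) * EPOCHS_PER_DAY + round(nap_start_h * 120) + 1
        nlen <- max(2L, round(nap_dur * 120))
        nrange <- nidx:min(nidx + nlen - 1, n_ep)
        # keep a >=30-min wake buffer so naps never merge with other sleep
        guard <- max(1, nidx - 61):min(nidx + nlen + 60, n_ep)
        if (nidx >= onset_idx - 62 || !all(labels[guard] == "WAKE")) next
        nap_lab <- rep("N2", length(nrange))
        nap_lab[1] <- "N1"
        if (length(nrange) > 60) nap_lab[30:45] <- "N3"
        labels[nrange] <- nap_lab
        periods[[length(periods) + 1]] <- data.frame(
          onset = timestamp[nrange[1]],
          offset = timestamp[nrange[length(nrange)]] + EPOCH_SEC,
          kind = "nap", day = d)
      }
    }

    # --- dropouts and artifacts --------------------------------------------
    missing_frac <- rep(0, n_ep)
    artifact <- rep(FALSE, n_ep)
    for (d in seq_len(n_days)) {
      dr <- ov(d, "dropout_rate", params$dropout_rate)
      didx <- (d - 1) * EPOCHS_PER_DAY + seq_len(EPOCHS_PER_DAY)
      if (dr > 0) missing_frac[didx][stats::runif(EPOCHS_PER_DAY) < dr] <- 1
    }
    if (params$artifact_rate > 0)
      artifact[stats::runif(n_ep) < params$artifact_rate] <- TRUE

    out <- list(hypnogram = hypnogram(timestamp, labels),
                artifact = artifact,
                missing_frac = missing_frac,
                periods = do.call(rbind, periods),
                cycles = if (length(cycles)) do.call(rbind, cycles) else NULL,
                params = params)
    class(out) <- "synthetic_hypnogram"
    out
  })
}

# Assemble one night's epoch labels. Returns labels plus the 1-based epoch
# index (within the night) at which each cycle's REM period starts.
build_night <- function(params, dur_h, waso, rem_shift) {
  lead_ep <- max(4L, round(params$sleep_onset_latency * 120))
  total_ep <- max(lead_ep + 8L * params$n_cycles, round(dur_h * 120))
  raw <- params$cycle1_duration *
    params$cycle_duration_decay^(seq_len(params$n_cycles) - 1)
  cyc_ep <- pmax(8L, round(raw / sum(raw) * (total_ep - lead_ep)))

  lead <- rep("N2", lead_ep)
  lead[1:2] <- "N1"
  if (lead_ep > 8) lead[(lead_ep - 3):lead_ep] <- "N3"

  labels <- lead
  cycle_start <- integer(params$n_cycles)
  sp <- params$stage_proportions
  for (i in seq_len(params$n_cycles)) {
    props <- sp[i, ]
    if (rem_shift != 0) {
      rem <- min(max(props["REM"] + rem_shift, 0.02), 0.8)
      other <- props[c("N1", "N2", "N3")]
      props <- c(other / sum(other) * (1 - rem), REM = unname(rem))
      names(props) <- c("N1", "N2", "N3", "REM")
    }
    ne <- cyc_ep[i]
    rem_ep <- max(1L, round(props["REM"] * ne))
    nrem_ep <- ne - rem_ep
    n1 <- round(props["N1"] / sum(props[c("N1", "N2", "N3")]) * nrem_ep)
    n3 <- round(props["N3"] / sum(props[c("N1", "N2", "N3")]) * nrem_ep)
    n2 <- nrem_ep - n1 - n3
    n2a <- n2 %/% 2
    block <- c(rep("REM", rem_ep), rep("N1", n1), rep("N2", n2a),
               rep("N3", n3), rep("N2", n2 - n2a))
    cycle_start[i] <- length(labels) + 1L
    labels <- c(labels, block)
  }

  # brief arousals: never the period endpoints nor a cycle's first REM epoch
  if (waso > 0) {
    protected <- c(1L, length(labels), cycle_start)
    cand <- setdiff(seq_along(labels), protected)
    flip <- cand[stats::runif(length(cand)) < waso]
    labels[flip] <- "WAKE"
  }
  list(labels = labels, cycle_start = cycle_start)
}
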