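#' Detect sleep periods (main sleep and naps) in a hypnogram
#'
#' Maximal runs of sleep stages are found and merged across wake gaps
#' shorter than `gap_merge_min`; wake inside a merged period is counted as
#' WASO (wake after sleep onset). Runs consisting solely of N1 that are not
#' adjacent (within the merge window) to more substantive sleep are ignored
#' entirely, following the rule that spontaneous isolated NREM1 is not
#' counted as sleep. A period must contain at least one contiguous sleep
#' run of `min_seed_min` minutes; periods shorter than 2 h are classed as
#' naps.
#'
#' @param h a pruned [hypnogram()].
#' @param gap_merge_min wake gaps shorter than this (minutes) stay inside
#'   the period (default 30).
#' @param min_seed_min minimum contiguous sleep run to seed a period
#'   (default 10).
#' @return data.frame with columns `onset`, `offset` (POSIXct), `kind`
#'   (`"main"`/`"nap"`), `duration_h`, `waso_min`, and per-stage minutes
#'   `n1_min`, `n2_min`, `n3_min`, `rem_min`.
#' @export
detect_sleep_periods <- function(h, gap_merge_min = 30, min_seed_min = 10) {
  empty <- data.frame(onset = as.POSIXct(character(), tz = "UTC"),
                      offset = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), duration_h = numeric(),
                      waso_min = numeric(), n1_min = numeric(),
                      n2_min = numeric(), n3_min = numeric(),
                      rem_min = numeric())
  if (nrow(h) == 0) return(empty)
  lab <- as.character(h$label)
  is_sleep <- lab %in% SLEEP_STAGES
  runs <- run_segments(is_sleep)
  runs <- runs[runs$value, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  # drop isolated N1-only runs: kept only when within the merge window of a
  # run containing N2/N3/REM
  substantive <- vapply(seq_len(nrow(runs)), function(i)
    any(lab[runs$start[i]:runs$end[i]] %in% c("N2", "N3", "REM")), TRUE)
  gap_ep <- gap_merge_min * 60 / EPOCH_SEC
  keep <- substantive
  for (i in which(!substantive)) {
    near <- which(substantive &
                    (abs(runs$start - runs$end[i]) <= gap_ep |
                     abs(runs$start[i] - runs$end) <= gap_ep))
    if (length(near)) keep[i] <- TRUE
  }
  runs <- runs[keep, , drop = FALSE]
  substantive <- substantive[keep]
  if (nrow(runs) == 0) return(empty)

  # merge runs across short wake gaps
  grp <- cumsum(c(1, as.integer(
    runs$start[-1] - runs$end[-nrow(runs)] - 1 >= gap_ep)))
  out <- lapply(split(seq_len(nrow(runs)), grp), function(ii) {
    s <- runs$start[ii[1]]; e <- runs$end[ii[length(ii)]]
    seg <- lab[s:e]
    longest <- max(runs$end[ii] - runs$start[ii] + 1)
    if (longest * EPOCH_SEC / 60 < min_seed_min) return(NULL)
    if (!any(substantive[ii])) return(NULL)
    dur_h <- length(seg) * EPOCH_SEC / 3600
    data.frame(onset = h$timestamp[s],
               offset = h$timestamp[e] + EPOCH_SEC,
               kind = if (dur_h < 2) "nap" else "main",
               duration_h = dur_h,
               waso_min = sum(seg == "WAKE") * EPOCH_SEC / 60,
               n1_min = sum(seg == "N1") * EPOCH_SEC / 60,
               n2_min = sum(seg == "N2") * EPOCH_SEC / 60,
               n3_min = sum(seg == "N3") * EPOCH_SEC / 60,
               rem_min = sum(seg == "REM") * EPOCH_SEC / 60)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) empty else {rownames(out) <- NULL; out}
}

#' Per-day sleep metrics
#'
#' Periods are assigned to noon-to-noon 24-h windows by their onset time.
#' Total sleep is the sum of period durations (main sleep plus naps,
#' including WASO). State proportions are computed over total sleep; the
#' unknown fraction over the full 24 h.
#'
#' @param periods output of [detect_sleep_periods()].
#' @param h the hypnogram the periods came from (for the unknown fraction).
#' @return data.frame with one row per day key: `day`, `total_sleep_h`,
#'   `nap_count`, `waso_prop`, `n1_prop`, `n2_prop`, `n3_prop`, `rem_prop`,
#'   `unknown_frac`.
#' @export
daily_metrics <- function(periods, h) {
  keys <- sort(unique(day_key(h$timestamp)))
  unk <- tapply(as.character(h$label) == "UNKNOWN", day_key(h$timestamp), mean)
  if (nrow(periods) > 1) {
    o <- order(periods$onset)
    if (any(periods$onset[o][-1] < periods$offset[o][-nrow(periods)]))
      stop("overlapping sleep periods")
  }
  pk <- if (nrow(periods)) day_key(periods$onset) else as.Date(character())
  rows <- lapply(keys, function(k) {
    pp <- periods[pk == k, , drop = FALSE]
    tot_min <- sum(pp$duration_h) * 60
    props <- if (tot_min > 0) {
      c(sum(pp$waso_min), sum(pp$n1_min), sum(pp$n2_min),
        sum(pp$n3_min), sum(pp$rem_min)) / tot_min
    } else rep(NA_real_, 5)
    data.frame(day = k, total_sleep_h = tot_min / 60,
               nap_count = sum(pp$kind == "nap"),
               waso_prop = props[1], n1_prop = props[2], n2_prop = props[3],
               n3_prop = props[4], rem_prop = props[5],
               unknown_frac = unname(unk[as.character(k)]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment a main sleep period into sleep cycles
#'
#' REM periods are maximal REM runs with interruptions shorter than
#' `rem_gap_min` minutes merged. Cycle one spans from the start of the
#' first REM period to the start of the next; each subsequent cycle runs
#' from one REM-period start to the next. At most five cycles are retained.
#'
#' @param h hypnogram restricted to one main sleep period (or a full
#'   hypnogram together with `onset`/`offset`).
#' @param onset,offset optional POSIXct bounds of the period.
#' @param rem_gap_min REM interruptions shorter than this merge into one
#'   REM period (default 10).
#' @param max_cycles cycles retained (default 5).
#' @return data.frame with `index`, `start`, `end`, `duration_h` and
#'   per-stage proportions `waso_prop`, `n1_prop`, `n2_prop`, `n3_prop`,
#'   `rem_prop`; zero rows when fewer than two REM periods exist.
#' @export
segment_cycles <- function(h, onset = NULL, offset = NULL,
                           rem_gap_min = 10, max_cycles = 5) {
  if (!is.null(onset))
    h <- h[h$timestamp >= onset & h$timestamp < offset, , drop = FALSE]
  lab <- as.character(h$label)
  empty <- data.frame(index = integer(), start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_h = numeric(), waso_prop = numeric(),
                      n1_prop = numeric(), n2_prop = numeric(),
                      n3_prop = numeric(), rem_prop = numeric())
  if (!any(lab == "REM")) return(empty)
  runs <- run_segments(lab == "REM")
  runs <- runs[runs$value, , drop = FALSE]
  # merge REM runs separated by gaps shorter than rem_gap_min
  gap_ep <- rem_gap_min * 60 / EPOCH_SEC
  grp <- cumsum(c(1, as.integer(
    runs$start[-1] - runs$end[-nrow(runs)] - 1 >= gap_ep)))
  rem_starts <- vapply(split(runs$start, grp), min, 1)
  if (length(rem_starts) < 2) return(empty)
  n_cyc <- min(length(rem_starts) - 1, max_cycles)
  rows <- lapply(seq_len(n_cyc), function(i) {
    s <- rem_starts[i]; e <- rem_starts[i + 1] - 1
    seg <- lab[s:e]
    n <- length(seg)
    data.frame(index = i, start = h$timestamp[s],
               end = h$timestamp[e] + EPOCH_SEC,
               duration_h = n * EPOCH_SEC / 3600,
               waso_prop = sum(seg == "WAKE") / n,
               n1_prop = sum(seg == "N1") / n,
               n2_prop = sum(seg == "N2") / n,
               n3_prop = sum(seg == "N3") / n,
               rem_prop = sum(seg == "REM") / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Circular histogram and circular statistics of event clock times
#'
#' @param hours event times as hours-of-day in `[0, 24)`.
#' @param n_bins histogram bins around the clock (default 24).
#' @return list with `breaks` (hours), `mass` (normalized bin masses summing
#'   to 1), `mean_hour` (circular mean as hours-of-day) and
#'   `resultant_length` (mean resultant vector length in `[0, 1]`).
#' @export
circular_histogram <- function(hours, n_bins = 24) {
  if (length(hours) == 0) stop("no event times supplied")
  if (any(hours < 0 | hours >= 24)) stop("hours must lie in [0, 24)")
  breaks <- seq(0, 24, length.out = n_bins + 1)
  mass <- tabulate(findInterval(hours, breaks, rightmost.closed = TRUE),
                   nbins = n_bins) / length(hours)
  theta <- hours / 24 * 2 * pi
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mean_hour <- (atan2(S, C) / (2 * pi) * 24) %% 24
  # a negative angle within rounding error of zero must not wrap to 24
  if (24 - mean_hour < 1e-9) mean_hour <- 0
  list(breaks = breaks, mass = mass, mean_hour = mean_hour,
       resultant_length = sqrt(C^2 + S^2))
}
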