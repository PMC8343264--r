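test_that("generate_hypnogram is reproducible and well-formed", {
  sp <- sleep_params()
  a <- generate_hypnogram(sp, 3, seed = 11)
  b <- generate_hypnogram(sp, 3, seed = 11)
  expect_identical(as.character(a$hypnogram$label),
                   as.character(b$hypnogram$label))
  expect_identical(a$missing_frac, b$missing_frac)
  c2 <- generate_hypnogram(sp, 3, seed = 12)
  expect_false(identical(as.character(a$hypnogram$label),
                         as.character(c2$hypnogram$label)))
  expect_equal(nrow(a$hypnogram), 3 * 2880)
  # ground truth never contains UNKNOWN; missingness lives in the masks
  expect_false(any(as.character(a$hypnogram$label) == "UNKNOWN"))
  expect_true(all(a$missing_frac %in% c(0, 1)))
  expect_equal(length(a$artifact), nrow(a$hypnogram))
})

test_that("true periods match the labels and naps stay short", {
  synth <- generate_hypnogram(sleep_params(), 5, seed = 21)
  h <- synth$hypnogram
  per <- synth$periods
  expect_true(all(per$kind %in% c("main", "nap")))
  for (i in seq_len(nrow(per))) {
    sel <- h$timestamp >= per$onset[i] & h$timestamp < per$offset[i]
    seg <- as.character(h$label[sel])
    dur_h <- sum(sel) / 120
    if (per$kind[i] == "nap") {
      expect_lt(dur_h, 2)
    } else {
      expect_gte(dur_h, 2)
    }
    # endpoints of every generated period are asleep
    expect_true(seg[1] %in% c("N1", "N2", "N3", "REM"))
    expect_true(seg[length(seg)] %in% c("N1", "N2", "N3", "REM"))
  }
})

test_that("generating cycles start with REM and shrink across the night", {
  synth <- generate_hypnogram(sleep_params(), 30, seed = 31)
  h <- synth$hypnogram
  cyc <- synth$cycles
  expect_true(all(cyc$index >= 1 & cyc$index <= sleep_params()$n_cycles))
  # every recorded cycle starts on a REM epoch
  idx <- match(as.numeric(cyc$start), as.numeric(h$timestamp))
  expect_true(all(as.character(h$label)[idx] == "REM"))
  # mean duration decreases from first to last cycle
  dur <- as.numeric(cyc$end - cyc$start, units = "hours")
  m <- tapply(dur, cyc$index, mean)
  expect_gt(m[["1"]], m[[as.character(max(cyc$index))]])
})

test_that("overrides shift duration, WASO and REM as requested", {
  sp <- sleep_params(nap_rate_per_day = 0, dropout_rate = 0, artifact_rate = 0,
                     waso_fraction = 0.1)
  ov_long <- data.frame(day = 1, duration_h = 12)
  ov_short <- data.frame(day = 1, duration_h = 5)
  long <- generate_hypnogram(sp, 2, seed = 41, overrides = ov_long)
  short <- generate_hypnogram(sp, 2, seed = 41, overrides = ov_short)
  sleep_h <- function(s, d) {
    lab <- as.character(s$hypnogram$label)[(d - 1) * 2880 + 1:2880]
    sum(lab != "WAKE") / 120
  }
  expect_gt(sleep_h(long, 1), sleep_h(short, 1) + 4)

  ov_waso <- data.frame(day = 1, waso_shift = 0.3)
  wasoy <- generate_hypnogram(sp, 1, seed = 42, overrides = ov_waso)
  wason <- generate_hypnogram(sp, 1, seed = 42)
  frac_wake_inside <- function(s) {
    p <- s$periods[s$periods$kind == "main", ][1, ]
    sel <- s$hypnogram$timestamp >= p$onset & s$hypnogram$timestamp < p$offset
    mean(as.character(s$hypnogram$label)[sel] == "WAKE")
  }
  expect_gt(frac_wake_inside(wasoy), frac_wake_inside(wason) + 0.1)

  ov_rem <- data.frame(day = 1, rem_shift = 0.15)
  remy <- generate_hypnogram(sp, 1, seed = 43, overrides = ov_rem)
  remn <- generate_hypnogram(sp, 1, seed = 43)
  rem_frac <- function(s) {
    lab <- as.character(s$hypnogram$label)
    sum(lab == "REM") / sum(lab != "WAKE")
  }
  expect_gt(rem_frac(remy), rem_frac(remn) + 0.05)
})

test_that("sleep parameter validation rejects impossible settings", {
  expect_error(sleep_params(waso_fraction = 1.2), "waso")
  expect_error(sleep_params(n_cycles = 0), "cycle")
  expect_error(sleep_params(night_sleep_duration_mean = -1), "duration")
  bad <- sleep_params()
  bad$stage_proportions[1, ] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(validate_sleep_params(bad), "proportion")
})

test_that("simulate_category_days has the requested marginals and levels", {
  d <- simulate_category_days(4, 2000, seed = 8)
  expect_equal(nrow(d), 8000)
  expect_equal(levels(d$category), c("baseline", "decreased", "increased"))
  tab <- table(d$category) / nrow(d)
  expect_equal(unname(tab[["baseline"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(tab[["decreased"]]), 0.25, tolerance = 0.05)
})

test_that("generate_seizures respects the generating odds ratios", {
  d <- simulate_category_days(30, 1000, seed = 9)
  rp <- seizure_risk_params(or_decreased = 0.5, or_increased = 2,
                            random_intercept_sd = 0)
  g <- generate_seizures(d, rp, seed = 10)
  expect_equal(length(g$seizure_day), nrow(d))
  expect_true(all(g$seizure_day %in% 0:1))
  rate <- tapply(g$seizure_day, d$category, mean)
  odds <- rate / (1 - rate)
  expect_equal(unname(odds[["decreased"]] / odds[["baseline"]]), 0.5,
               tolerance = 0.15)
  expect_equal(unname(odds[["increased"]] / odds[["baseline"]]), 2,
               tolerance = 0.15)
  # events carry positive durations and states from the placement support
  expect_true(all(g$events$duration_s > 0))
  expect_true(all(g$events$state %in% stage_levels()))
})

test_that("seizure onsets land in epochs of the recorded state", {
  synth <- generate_hypnogram(sleep_params(), 8, seed = 51)
  d <- data.frame(patient = factor(rep("P1", 8)), day = 1:8,
                  category = factor(rep("baseline", 8),
                                    levels = c("baseline", "decreased",
                                               "increased")))
  rp <- seizure_risk_params(baseline_log_odds = 2)  # near-certain seizures
  g <- generate_seizures(d, rp, seed = 52,
                         hypnograms = list(P1 = synth$hypnogram))
  expect_gt(nrow(g$events), 0)
  t0 <- synth$hypnogram$timestamp[1]
  idx <- floor(as.numeric(g$events$onset - t0, units = "secs") / 30) + 1
  expect_identical(as.character(synth$hypnogram$label)[idx], g$events$state)
})

test_that("make_cohort assembles consistent day-level truth", {
  co <- make_cohort(3, n_days = 60, seed = 61)
  expect_s3_class(co, "cohort")
  days <- do.call(rbind, lapply(co$patients, `[[`, "day_truth"))
  seizures <- do.call(rbind, lapply(co$patients, `[[`, "events"))
  expect_equal(nrow(days), 3 * 60)
  expect_true(all(days$category %in% c("baseline", "decreased", "increased")))
  expect_true(all(days$seizure_day %in% 0:1))
  # seizure events exist exactly on seizure days
  key <- paste(days$patient, days$day)
  ev_key <- unique(paste(seizures$patient, seizures$day))
  expect_setequal(ev_key, key[days$seizure_day == 1])
  expect_output(print(co), "cohort")
  # reproducible
  co2 <- make_cohort(3, n_days = 60, seed = 61)
  days2 <- do.call(rbind, lapply(co2$patients, `[[`, "day_truth"))
  expect_identical(days$seizure_day, days2$seizure_day)
})

test_that("post-seizure feedback lengthens next-day sleep on average", {
  co <- make_cohort(4, n_days = 300, seed = 71)
  days <- do.call(rbind, lapply(co$patients, `[[`, "day_truth"))
  post <- unlist(lapply(split(days, days$patient), function(d) {
    d$duration_h[which(d$seizure_day[-nrow(d)] == 1) + 1]
  }))
  ctrl <- unlist(lapply(split(days, days$patient), function(d) {
    d$duration_h[which(d$seizure_day[-nrow(d)] == 0) + 1]
  }))
  expect_gt(mean(post), mean(ctrl))
})
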