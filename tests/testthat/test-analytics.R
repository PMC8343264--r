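test_that("a short sleep bout is a nap and a long one is main sleep", {
  nap <- toy_hypnogram(toy_day(c(rep("WAKE", 120),
                                 run_labels(N1 = 2, N2 = 100, N3 = 60, REM = 50))))
  per <- detect_sleep_periods(nap)
  expect_equal(nrow(per), 1)
  expect_equal(per$kind, "nap")
  expect_equal(per$duration_h, 212 / 120)

  main <- toy_hypnogram(toy_day(c(rep("WAKE", 120),
                                  run_labels(N1 = 4, N2 = 300, N3 = 100,
                                             REM = 80, N2 = 60))))
  per2 <- detect_sleep_periods(main)
  expect_equal(per2$kind, "main")
  expect_equal(per2$n2_min + per2$n3_min + per2$rem_min + per2$n1_min,
               544 * 0.5)
})

test_that("wake gaps under 30 minutes merge and count as WASO", {
  lab <- toy_day(c(rep("WAKE", 100),
                   run_labels(N2 = 120, WAKE = 40, N2 = 120)))  # 20-min gap
  per <- detect_sleep_periods(toy_hypnogram(lab))
  expect_equal(nrow(per), 1)
  expect_equal(per$waso_min, 20)
  expect_equal(per$duration_h, 280 / 120)

  lab2 <- toy_day(c(rep("WAKE", 100),
                    run_labels(N2 = 240, WAKE = 70, N2 = 240)))  # 35-min gap
  per2 <- detect_sleep_periods(toy_hypnogram(lab2))
  expect_equal(nrow(per2), 2)
  expect_equal(sum(per2$waso_min), 0)
})

test_that("isolated N1 is ignored; N1 near real sleep is kept", {
  iso <- toy_day(c(rep("WAKE", 100), rep("N1", 30),
                   rep("WAKE", 500), run_labels(N2 = 300, REM = 60)))
  per <- detect_sleep_periods(toy_hypnogram(iso))
  expect_equal(nrow(per), 1)
  expect_equal(per$n1_min, 0)  # the isolated bout is not part of any period

  near <- toy_day(c(rep("WAKE", 100), rep("N1", 30), rep("WAKE", 20),
                    run_labels(N2 = 300, REM = 60)))
  per2 <- detect_sleep_periods(toy_hypnogram(near))
  expect_equal(nrow(per2), 1)
  expect_equal(per2$n1_min, 15)
  expect_equal(per2$waso_min, 10)
})

test_that("daily metrics aggregate periods into noon-to-noon days", {
  lab <- c(toy_day(c(rep("WAKE", 1300),
                     run_labels(N1 = 4, N2 = 400, N3 = 200, REM = 116))),
           toy_day(c(rep("WAKE", 200), run_labels(N2 = 100, REM = 40))))
  h <- toy_hypnogram(lab)
  per <- detect_sleep_periods(h)
  dm <- daily_metrics(per, h)
  expect_equal(nrow(dm), 2)
  expect_equal(dm$day, as.Date(c("2020-01-01", "2020-01-02")))
  expect_equal(dm$total_sleep_h[1], 720 / 120)
  expect_equal(dm$nap_count, c(0, 1))
  props <- dm[1, c("waso_prop", "n1_prop", "n2_prop", "n3_prop", "rem_prop")]
  expect_equal(sum(props), 1)
  expect_equal(dm$rem_prop[1], 116 / 720)
  expect_equal(dm$unknown_frac, c(0, 0))
  # overlapping periods are a hard error
  bad <- per
  bad$onset[2] <- per$onset[1] + 60
  expect_error(daily_metrics(bad, h), "overlapping")
})

test_that("cycles run from REM start to REM start with short gaps merged", {
  lab <- toy_day(c(rep("WAKE", 10),
                   run_labels(N2 = 100, REM = 20, N2 = 80,
                              REM = 10, WAKE = 4, REM = 10,  # one REM period
                              N2 = 60, REM = 16, N2 = 40)))
  h <- toy_hypnogram(lab)
  cyc <- segment_cycles(h)
  expect_equal(nrow(cyc), 2)
  # cycle 1: REM@111 to the merged REM period start (epoch 211)
  expect_equal(cyc$start[1], T0 + 30 * 110)
  expect_equal(cyc$duration_h[1], 100 / 120)
  expect_equal(cyc$rem_prop[1], 20 / 100)
  # cycle 2 runs to the start of the third REM period
  expect_equal(cyc$duration_h[2], 84 / 120)
  # a >=10-min interruption splits REM periods instead
  lab2 <- toy_day(c(rep("WAKE", 10),
                    run_labels(N2 = 100, REM = 20, N2 = 80,
                               REM = 10, WAKE = 20, REM = 10, N2 = 40)))
  cyc2 <- segment_cycles(toy_hypnogram(lab2))
  expect_equal(nrow(cyc2), 2)
  # fewer than two REM periods: no cycles
  expect_equal(nrow(segment_cycles(toy_hypnogram(
    toy_day(run_labels(N2 = 100, REM = 20, N2 = 100))))), 0)
})

test_that("at most five cycles are retained", {
  one <- run_labels(REM = 10, N2 = 50)
  lab <- toy_day(c(rep("WAKE", 10), rep(one, 8)))
  cyc <- segment_cycles(toy_hypnogram(lab))
  expect_equal(nrow(cyc), 5)
  expect_equal(cyc$index, 1:5)
})

test_that("circular statistics match closed forms", {
  ch <- circular_histogram(c(23, 1))
  expect_equal(ch$mean_hour, 0)
  expect_equal(sum(ch$mass), 1)
  expect_equal(ch$resultant_length, cos(2 * pi / 24), tolerance = 1e-12)
  one <- circular_histogram(rep(6.5, 10))
  expect_equal(one$mean_hour, 6.5)
  expect_equal(one$resultant_length, 1)
  # antipodal points cancel
  expect_equal(circular_histogram(c(0, 12))$resultant_length, 0,
               tolerance = 1e-12)
  expect_error(circular_histogram(numeric(0)), "no event")
  expect_error(circular_histogram(c(1, 25)), "24")
})

test_that("recovered architecture trends match the generator", {
  synth <- generate_hypnogram(sleep_params(dropout_rate = 0,
                                           artifact_rate = 0,
                                           nap_rate_per_day = 0),
                              40, seed = 401)
  h <- synth$hypnogram
  per <- detect_sleep_periods(h)
  mains <- per[per$kind == "main", ]
  cyc <- do.call(rbind, lapply(seq_len(nrow(mains)), function(i)
    segment_cycles(h, mains$onset[i], mains$offset[i])))
  dur <- tapply(cyc$duration_h, cyc$index, mean)
  rem <- tapply(cyc$rem_prop, cyc$index, mean)
  n3 <- tapply(cyc$n3_prop, cyc$index, mean)
  k <- length(dur)
  expect_gte(k, 3)
  expect_gt(dur[["1"]], dur[[as.character(k)]])
  expect_lt(rem[["1"]], rem[[as.character(k)]])
  expect_gt(n3[["1"]], n3[[as.character(k)]])
})
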