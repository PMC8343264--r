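test_that("seizure states and the WASO rule annotate correctly", {
  lab <- toy_day(c(rep("WAKE", 100),
                   run_labels(N2 = 200, WAKE = 20, N3 = 100, REM = 60),
                   rep("UNKNOWN", 10)))
  h <- toy_hypnogram(lab)
  per <- detect_sleep_periods(h)
  sz <- data.frame(onset = T0 + 30 * c(10, 150, 310, 450, 481),
                   duration_s = rep(30, 5))
  ann <- annotate_seizure_states(sz, h, per)
  expect_equal(ann$state, c("WAKE", "N2", "WAKE", "REM", "UNKNOWN"))
  expect_equal(ann$waso, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$during_sleep, c(FALSE, TRUE, TRUE, TRUE, NA))
  expect_error(annotate_seizure_states(
    data.frame(onset = T0 - 1), h), "outside")
})

test_that("per-state rates divide counts by recorded hours", {
  lab <- toy_day(run_labels(WAKE = 240, N2 = 120, REM = 120))
  h <- toy_hypnogram(lab)
  sz <- data.frame(onset = T0 + 30 * c(250, 260, 370),
                   duration_s = c(60, 120, 60))
  ann <- annotate_seizure_states(sz, h)
  # N1 and N3 have no recorded time: both warn, both are omitted
  expect_warning(expect_warning(
    tab <- seizure_rate_duration_by_state(ann, h), "N1"), "N3")
  expect_false(any(tab$state %in% c("N1", "N3")))
  n2 <- tab[tab$state == "N2", ]
  expect_equal(n2$n_seizures, 2)
  expect_equal(n2$rate_per_h, 2 / 1)
  expect_equal(n2$mean_duration_min, 1.5)
  rem <- tab[tab$state == "REM", ]
  expect_equal(rem$rate_per_h, 1)
})

test_that("IQR categorization matches quantile() on seizure-free days", {
  set.seed(601)
  v <- rnorm(100, 8, 1)
  sz <- rbinom(100, 1, 0.2)
  days <- data.frame(patient = "P1", day = 1:100, total_sleep_h = v,
                     seizure_day = sz)
  out <- categorize_days(days, "total_sleep_h")
  q <- quantile(v[sz == 0], c(0.25, 0.75), names = FALSE)
  expect_equal(as.character(out$category[sz == 1]),
               rep("excluded", sum(sz)))
  free <- sz == 0
  expect_equal(as.character(out$category[free & v < q[1]]),
               rep("decreased", sum(free & v < q[1])))
  expect_equal(as.character(out$category[free & v > q[2]]),
               rep("increased", sum(free & v > q[2])))
  expect_equal(as.character(out$category[free & v >= q[1] & v <= q[2]]),
               rep("baseline", sum(free & v >= q[1] & v <= q[2])))
  th <- attr(out, "thresholds")
  expect_equal(c(th$p25, th$p75), q)
  # patients with too few seizure-free days are skipped with a warning
  tiny <- data.frame(patient = "P2", day = 1:6,
                     total_sleep_h = rnorm(6, 8), seizure_day = 0)
  expect_warning(out2 <- categorize_days(tiny, "total_sleep_h"), "fewer")
  expect_true(all(is.na(out2$category)))
})

test_that("the 48-h outcome window starts at the day's end", {
  days <- data.frame(patient = "P1", day = as.Date("2020-01-01"))
  end <- as.POSIXct("2020-01-02 12:00:00", tz = "UTC")
  inside <- data.frame(patient = "P1", onset = end + 47 * 3600)
  at_end <- data.frame(patient = "P1", onset = end)       # not after the end
  beyond <- data.frame(patient = "P1", onset = end + 48.5 * 3600)
  expect_equal(outcome_within_48h(days, inside)$outcome, 1L)
  expect_equal(outcome_within_48h(days, at_end)$outcome, 0L)
  expect_equal(outcome_within_48h(days, beyond)$outcome, 0L)
  # exactly 48 h after the end is still inside (closed right endpoint)
  edge <- data.frame(patient = "P1", onset = end + 48 * 3600)
  expect_equal(outcome_within_48h(days, edge)$outcome, 1L)
  # other patients' seizures never count
  other <- data.frame(patient = "P2", onset = end + 3600)
  expect_equal(outcome_within_48h(days, other)$outcome, 0L)
})

test_that("rm_anova matches aov and the paired t-test", {
  set.seed(602)
  x <- matrix(rnorm(8 * 3, mean = rep(c(0, 0.5, 1), each = 8)), 8, 3)
  a <- rm_anova(x)
  df <- data.frame(y = as.vector(x),
                   subj = factor(rep(1:8, 3)),
                   cond = factor(rep(1:3, each = 8)))
  ref <- summary(aov(y ~ cond + Error(subj / cond), df))
  Fref <- ref[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(a$F, Fref, tolerance = 1e-10)
  expect_equal(a$df1 / a$epsilon, 2)
  # k = 2: F equals the squared paired t statistic and epsilon is 1
  x2 <- x[, 1:2]
  a2 <- rm_anova(x2)
  tt <- t.test(x2[, 1], x2[, 2], paired = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$epsilon, 1)
  expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Greenhouse-Geisser epsilon hits its closed-form bounds", {
  # compound symmetry: epsilon = 1
  S <- matrix(0.3, 4, 4); diag(S) <- 1
  expect_equal(gg_epsilon(S), 1)
  # rank-one between-condition structure drives epsilon to its floor
  v <- c(1, 2, 4, 8)
  S1 <- outer(v, v) + diag(1e-8, 4)
  expect_equal(gg_epsilon(S1), 1 / 3, tolerance = 1e-4)
  # never outside [1/(k-1), 1]
  set.seed(603)
  for (i in 1:10) {
    A <- matrix(rnorm(25), 5)
    e <- gg_epsilon(crossprod(A))
    expect_gte(e, 1 / 4)
    expect_lte(e, 1)
  }
})

test_that("Dunnett with two conditions reduces to the paired t-test", {
  set.seed(604)
  x <- matrix(rnorm(12 * 2, mean = rep(c(0, 0.6), each = 12)), 12, 2)
  colnames(x) <- c("control", "treat")
  dn <- dunnett_vs_control(x, control = 1)
  tt <- t.test(x[, 2], x[, 1], paired = TRUE)
  expect_equal(dn$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(dn$p_value, tt$p.value, tolerance = 1e-6)
  expect_equal(dn$estimate, mean(x[, 2]) - mean(x[, 1]))
})

test_that("bounded data are arcsine transformed and validated", {
  set.seed(605)
  p <- matrix(runif(10 * 3, 0.1, 0.4), 10, 3)
  a <- rm_anova(p, bounded = TRUE)
  expect_equal(a$F, rm_anova(asin(sqrt(p)))$F)
  expect_error(rm_anova(p * 10, bounded = TRUE), "\\[0, 1\\]")
  both <- rm_anova_postseizure(p, bounded = TRUE)
  expect_named(both, c("anova", "dunnett"))
  expect_equal(nrow(both$dunnett), 2)
})

test_that("bootstrap difference of means is calibrated and reproducible", {
  set.seed(606)
  a <- rnorm(60, 1); b <- rnorm(80, 0)
  bt <- bootstrap_mean_difference(a, b, n_boot = 2000, seed = 607)
  expect_equal(bt$diff, mean(a) - mean(b))
  expect_length(bt$boot, 2000)
  expect_lt(bt$ci[1], bt$diff)
  expect_gt(bt$ci[2], bt$diff)
  bt2 <- bootstrap_mean_difference(a, b, n_boot = 2000, seed = 607)
  expect_identical(bt$boot, bt2$boot)
  expect_warning(bootstrap_mean_difference(a, b, n_boot = 50, seed = 1),
                 "unstable")
  expect_error(bootstrap_mean_difference(numeric(0), b), "nonempty")
})
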