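fs <- 64

test_that("Welch PSD satisfies Parseval within 1%", {
  set.seed(201)
  # average over epochs: the single-epoch integral fluctuates with the taper
  n_ep <- 20
  X <- matrix(rnorm(30 * fs * n_ep), 30 * fs)
  tot <- vapply(seq_len(n_ep), function(j) {
    psd <- compute_psd(X[, j], fs)
    sum(psd$psd) * psd$df
  }, 0)
  expect_equal(mean(tot), mean(apply(X, 2, var)), tolerance = 0.01)
})

test_that("flat-spectrum relative powers equal bandwidth ratios", {
  set.seed(202)
  bands <- eeg_bands()
  widths <- bands$high_hz - bands$low_hz
  rel <- matrix(0, 30, 5)
  for (j in 1:30) {
    psd <- compute_psd(rnorm(30 * fs), fs)
    rel[j, ] <- band_powers(psd, bands)$rel_power
  }
  # relative power is band width over the 24-Hz (1-25 Hz) broadband width
  expect_equal(colMeans(rel), widths / 24, tolerance = 0.02)
})

test_that("pure-tone dominant and median frequencies are bin-exact", {
  t <- seq_len(30 * fs) / fs
  x <- sin(2 * pi * 10 * t)  # 10 Hz lies on the 0.25 Hz Welch grid
  psd <- compute_psd(x, fs)
  st <- frequency_stats(psd)
  expect_equal(unname(st["dominant"]), 10)
  expect_lt(abs(st["median"] - 10), psd$df + 1e-12)
})

test_that("spectral entropy attains its 0 and 1 limits", {
  freq <- seq(0, 32, by = 0.25)
  flat <- list(freq = freq, psd = rep(1, length(freq)), df = 0.25)
  expect_equal(spectral_entropy(flat, 1, 25), 1)
  spike <- list(freq = freq, psd = as.numeric(freq == 10), df = 0.25)
  expect_equal(spectral_entropy(spike, 1, 25), 0)
  # two equal bins among N give log(2)/log(N)
  two <- list(freq = freq, psd = as.numeric(freq %in% c(5, 10)), df = 0.25)
  N <- sum(freq >= 1 & freq < 25)
  expect_equal(spectral_entropy(two, 1, 25), log(2) / log(N))
  expect_error(spectral_entropy(flat, 1, 1.1), "2 frequency bins")
})

test_that("wavelet detail energies localize a tone in the right band", {
  t <- seq_len(30 * fs) / fs
  # 2.5 Hz tone -> third listed level (2-4 Hz); 12 Hz -> first (8-16 Hz)
  e_low <- wavelet_energies(sin(2 * pi * 2.5 * t), fs)
  expect_equal(which.max(e_low), 3)
  e_high <- wavelet_energies(sin(2 * pi * 12 * t), fs)
  expect_equal(which.max(e_high), 1)
  # white noise splits energy dyadically: ~1/4, 1/8, 1/16 of the total
  set.seed(203)
  e_wn <- rowMeans(vapply(1:20, function(i)
    wavelet_energies(rnorm(30 * fs), fs), numeric(3)))
  expect_equal(e_wn, c(1 / 4, 1 / 8, 1 / 16), tolerance = 0.05)
})

test_that("wavelet energies demand a dyadic sampling rate", {
  expect_error(wavelet_energies(rnorm(30 * 50), 50), "16")
})

test_that("extract_features returns the canonical 21 columns with NA bad rows", {
  set.seed(204)
  X <- matrix(rnorm(30 * fs * 6), 30 * fs)
  bad <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  ft <- extract_features(X, fs, bad = bad)
  expect_equal(dim(ft), c(6, 21))
  expect_identical(colnames(ft), feature_names())
  expect_true(all(is.na(ft[bad, ])))
  expect_true(all(!is.na(ft[!bad, ])))
  # matrix and vector inputs agree
  ft2 <- extract_features(as.vector(X[, 1]), fs)
  expect_equal(unname(ft2[1, ]), unname(ft[1, ]))
  # consistency with the single-epoch reference path
  psd <- compute_psd(X[, 1], fs)
  bp <- band_powers(psd)
  expect_equal(unname(ft[1, paste0("rel_power_", eeg_bands()$name)]),
               bp$rel_power)
  expect_equal(unname(ft[1, "spectral_median_freq"]),
               unname(frequency_stats(psd)["median"]))
  expect_equal(unname(ft[1, paste0("wavelet_rel_energy_d", 1:3)]),
               wavelet_energies(X[, 1], fs))
})

test_that("quantile normalization is invertible and flags constants", {
  set.seed(205)
  x <- cbind(a = rnorm(100), b = runif(100, 5, 9), c = rep(2, 100))
  qn <- quantile_normalize(x)
  expect_false(qn$params$usable[3])
  expect_true(all(is.na(qn$x[, 3])))
  inside <- qn$x[, 1] > -0.5 & qn$x[, 1] < 1.5
  back <- quantile_denormalize(qn$x, qn$params)
  expect_equal(back[inside, 1], x[inside, 1])
  expect_true(all(qn$x[, 1:2] >= -0.5 & qn$x[, 1:2] <= 1.5))
  # refitting vs applying stored parameters agree
  qn2 <- quantile_normalize(x, qn$params)
  expect_equal(qn2$x, qn$x)
  expect_error(quantile_normalize(x[1:10, ]), "20")
})

test_that("degenerate signals are rejected loudly", {
  expect_error(compute_psd(rep(0, 30 * fs), fs), "degenerate")
  expect_error(compute_psd(rep(NA_real_, 30 * fs), fs), "non-finite")
  expect_error(compute_psd(rnorm(100), fs), "30 s")
  expect_error(wavelet_energies(rep(0, 30 * fs), fs), "degenerate")
})

test_that("synthesized signals carry the generating spectral ordering", {
  sm <- signal_model(sampling_rate = fs)
  h <- toy_hypnogram(c(rep("N3", 10), rep("WAKE", 10), rep("UNKNOWN", 2)))
  sig <- generate_signal(h, sm, seed = 206)
  expect_equal(dim(sig$signal), c(30 * fs, 22))
  expect_true(all(is.na(sig$signal[, 21:22])))
  ft <- extract_features(sig$signal, fs, bad = c(rep(FALSE, 20), TRUE, TRUE))
  # N3 is delta-dominant and higher-amplitude than WAKE
  expect_gt(mean(ft[1:10, "rel_power_delta"]),
            mean(ft[11:20, "rel_power_delta"]) + 0.3)
  expect_gt(mean(ft[1:10, "abs_power_delta"]),
            mean(ft[11:20, "abs_power_delta"]))
  # reproducible
  sig2 <- generate_signal(h, sm, seed = 206)
  expect_identical(sig$signal, sig2$signal)
})
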