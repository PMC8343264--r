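#' Canonical EEG frequency bands
#'
#' Five analysis bands (delta 1-3, theta 3-7, alpha 7-12, low-beta 12-15,
#' high-beta 15-20 Hz) plus the 1-25 Hz broadband used for total power and
#' broadband entropy. Band edges are half-open `[low, high)` so shared edges
#' are never double-counted.
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "lowbeta", "highbeta"),
             low_hz = c(1, 3, 7, 12, 15),
             high_hz = c(3, 7, 12, 15, 20))
}

BROADBAND <- c(1, 25)

#' Canonical names of the 21 per-epoch features
#'
#' Order is stable: mean dominant frequency, spectral median frequency, five
#' absolute band powers, five relative band powers, five band entropies, the
#' 1-25 Hz broadband entropy, and three relative wavelet detail energies
#' (approximately 8-16, 4-8 and 2-4 Hz).
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  b <- eeg_bands()$name
  c("mean_dominant_freq", "spectral_median_freq",
    paste0("abs_power_", b), paste0("rel_power_", b),
    paste0("entropy_", b), "entropy_broadband",
    paste0("wavelet_rel_energy_d", 1:3))
}

#' Welch power spectral density of one 30-s epoch
#'
#' 4-s Hann-tapered windows with 50% overlap, averaged one-sided
#' periodograms scaled as a density so that the integral over frequency
#' matches the tapered signal variance.
#'
#' @param x numeric vector of `30 * fs` finite samples.
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz), `psd` (density, units^2/Hz), `df` (grid
#'   step) and `dom_freq` (mean over windows of the 1-25 Hz peak frequency).
#' @export
compute_psd <- function(x, fs) {
  if (anyNA(x) || any(!is.finite(x))) stop("epoch contains non-finite values")
  if (length(x) != round(30 * fs))
    stop("epoch must contain exactly 30 s x fs samples")
  if (all(x == 0)) stop("degenerate signal: all-zero epoch")
  w <- welch_psd(matrix(x, ncol = 1), fs)
  list(freq = w$freq, psd = w$psd[, 1], df = w$df, dom_freq = w$dom_freq[1])
}

# Vectorised Welch PSD over epochs (columns of X). Returns one-sided density
# matrix (freq x epochs) plus the per-epoch mean peak frequency in 1-25 Hz.
welch_psd <- function(X, fs) {
  n <- nrow(X)
  nw <- round(4 * fs)
  step <- nw %/% 2
  starts <- seq(1, n - nw + 1, by = step)
  K <- ncol(X)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / nw)  # periodic Hann
  u <- sum(win^2)
  nf <- nw %/% 2 + 1
  freq <- (seq_len(nf) - 1) * fs / nw

  # stack all windows of all epochs column-wise and FFT once
  seg_idx <- outer(seq_len(nw) - 1L, starts, `+`)          # nw x nwin
  big <- matrix(X[as.vector(seg_idx), ], nrow = nw)        # nw x (nwin*K)
  big <- big * win
  sp <- abs(stats::mvfft(big))^2                            # power per window
  sp <- sp[seq_len(nf), , drop = FALSE]

  in_bb <- freq >= BROADBAND[1] & freq < BROADBAND[2]
  peak_rows <- which(in_bb)
  peak_f <- freq[peak_rows][max.col(t(sp[peak_rows, , drop = FALSE]),
                                    ties.method = "first")]
  nwin <- length(starts)
  dom_freq <- colMeans(matrix(peak_f, nrow = nwin))

  # average windows within each epoch, scale to one-sided density
  dim(sp) <- c(nf * nwin, K)
  psd <- matrix(0, nf, K)
  for (j in seq_len(nwin))
    psd <- psd + matrix(sp[(j - 1) * nf + seq_len(nf), ], nf, K)
  psd <- psd / nwin * (2 / (fs * u))
  psd[1, ] <- psd[1, ] / 2
  if (nw %% 2 == 0) psd[nf, ] <- psd[nf, ] / 2
  list(freq = freq, psd = psd, df = fs / nw, dom_freq = dom_freq)
}

#' Absolute and relative band powers from a PSD
#'
#' Relative power is the band integral divided by the total 1-25 Hz
#' integral.
#'
#' @param psd list as returned by [compute_psd()].
#' @param bands data.frame as [eeg_bands()].
#' @return data.frame with `name`, `abs_power`, `rel_power`.
#' @export
band_powers <- function(psd, bands = eeg_bands()) {
  if (max(bands$high_hz) > max(psd$freq) + 1e-9)
    stop("bands extend beyond the PSD frequency range")
  total <- band_integral(psd, BROADBAND[1], BROADBAND[2])
  if (total <= 0) stop("degenerate signal: zero total 1-25 Hz power")
  ab <- mapply(function(lo, hi) band_integral(psd, lo, hi),
               bands$low_hz, bands$high_hz)
  data.frame(name = bands$name, abs_power = ab, rel_power = ab / total)
}

band_integral <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  sum(psd$psd[sel]) * psd$df
}

#' Mean dominant and spectral median frequency
#'
#' The dominant frequency is the mean over Welch windows of the 1-25 Hz
#' spectral peak; the median frequency splits the cumulative 1-25 Hz power
#' into equal halves (linear interpolation between bins).
#'
#' @param psd list as returned by [compute_psd()].
#' @return named numeric vector `c(dominant =, median =)`.
#' @export
frequency_stats <- function(psd) {
  sel <- psd$freq >= BROADBAND[1] & psd$freq < BROADBAND[2]
  p <- psd$psd[sel]; f <- psd$freq[sel]
  if (sum(p) <= 0) stop("degenerate signal: zero in-band power")
  med <- cumpower_median(f, p)
  dom <- psd$dom_freq %||% f[which.max(p)]
  c(dominant = dom, median = med)
}

cumpower_median <- function(f, p) {
  cp <- cumsum(p)
  half <- cp[length(cp)] / 2
  i <- which(cp >= half)[1]
  if (i == 1) return(f[1])
  # linear interpolation within the bin that crosses the half-power point
  f[i - 1] + (f[i] - f[i - 1]) * (half - cp[i - 1]) / (cp[i] - cp[i - 1])
}

#' Normalized spectral entropy within a band
#'
#' Shannon entropy of the within-band normalized PSD, divided by the log of
#' the number of bins, hence in `[0, 1]`: 0 for a single tone, 1 for a flat
#' spectrum.
#'
#' @param psd list as returned by [compute_psd()].
#' @param low_hz,high_hz half-open band edges.
#' @return numeric scalar in `[0, 1]`.
#' @export
spectral_entropy <- function(psd, low_hz, high_hz) {
  sel <- psd$freq >= low_hz & psd$freq < high_hz
  if (sum(sel) < 2) stop("band must contain at least 2 frequency bins")
  p <- psd$psd[sel]
  s <- sum(p)
  if (s <= 0) stop("degenerate signal: zero band power")
  p <- p / s
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(sum(sel))
}

# Daubechies-4 (db4, 8-tap) orthonormal analysis filters.
DB4_H <- c(0.230377813308855, 0.714846570552542, 0.630880767929590,
           -0.027983769416984, -0.187034811718881, 0.030841381835987,
           0.032883011666983, -0.010597401784997)
DB4_G <- rev(DB4_H) * (-1)^(seq_along(DB4_H) - 1)

# One periodic DWT analysis step on columns of X (rows = samples, even count).
dwt_step <- function(X, filt) {
  n <- nrow(X)
  half <- n %/% 2L
  out <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L)
  for (k in seq_along(filt)) {
    rows <- (base + k - 1L) %% n + 1L
    out <- out + filt[k] * X[rows, , drop = FALSE]
  }
  out
}

# Energies of detail levels 1..L for columns of X (periodic db4 pyramid).
dwt_detail_energies <- function(X, L) {
  A <- X
  E <- matrix(NA_real_, L, ncol(X))
  for (l in seq_len(L)) {
    if (nrow(A) %% 2L == 1L) A <- rbind(A, A[1, , drop = FALSE])
    D <- dwt_step(A, DB4_G)
    A <- dwt_step(A, DB4_H)
    E[l, ] <- colSums(D^2)
  }
  E
}

#' Relative discrete-wavelet detail energies
#'
#' Energies of the three db4 detail levels whose dyadic bands cover
#' approximately 8-16, 4-8 and 2-4 Hz (level bands are
#' `[fs/2^(l+1), fs/2^l]`, so the levels used adapt to the sampling rate),
#' each divided by the total signal energy.
#'
#' @param x numeric vector of `30 * fs` samples.
#' @param fs sampling rate in Hz; must place 16 Hz on a dyadic edge
#'   (fs = 16 * 2^m), e.g. 64, 128, 256.
#' @return numeric vector of length 3 (relative energies, sum <= 1).
#' @export
wavelet_energies <- function(x, fs) {
  if (anyNA(x) || any(!is.finite(x))) stop("epoch contains non-finite values")
  if (all(x == 0)) stop("degenerate signal: all-zero epoch")
  l0 <- log2(fs / 16)
  if (abs(l0 - round(l0)) > 1e-9 || l0 < 1)
    stop("sampling rate must be 16 * 2^m Hz for dyadic wavelet bands")
  l0 <- round(l0)
  E <- dwt_detail_energies(matrix(x, ncol = 1), l0 + 2L)
  tot <- sum(x^2)
  as.vector(E[l0 + (0:2), 1] / tot)
}

#' Extract the 21 per-epoch features from a continuous signal
#'
#' Splits the signal into contiguous 30-s epochs and computes, per epoch,
#' the canonical feature set ([feature_names()]). Epochs flagged as bad
#' (artifact or mostly missing) yield a row of `NA`.
#'
#' @param signal numeric vector (length a multiple of `30 * fs`) or a
#'   `samples x epochs` matrix.
#' @param fs sampling rate, Hz.
#' @param bad optional logical vector, one per epoch; `TRUE` rows are
#'   returned as missing.
#' @param chunk_size epochs processed per FFT batch (memory control).
#' @return numeric matrix `epochs x 21` with canonical column names.
#' @export
extract_features <- function(signal, fs, bad = NULL, chunk_size = 256L) {
  if (!is.matrix(signal)) {
    n_ep <- length(signal) / (30 * fs)
    if (abs(n_ep - round(n_ep)) > 1e-9)
      stop("signal length must be a multiple of 30 s x fs")
    signal <- matrix(signal, nrow = 30 * fs)
  }
  K <- ncol(signal)
  if (is.null(bad)) bad <- rep(FALSE, K)
  stopifnot(length(bad) == K)
  out <- matrix(NA_real_, K, 21, dimnames = list(NULL, feature_names()))
  good <- which(!bad)
  l0 <- round(log2(fs / 16))
  for (i in split(good, ceiling(seq_along(good) / chunk_size))) {
    X <- signal[, i, drop = FALSE]
    w <- welch_psd(X, fs)
    bands <- eeg_bands()
    in_bb <- w$freq >= BROADBAND[1] & w$freq < BROADBAND[2]
    total <- colSums(w$psd[in_bb, , drop = FALSE]) * w$df
    ab <- sapply(seq_len(nrow(bands)), function(b) {
      sel <- w$freq >= bands$low_hz[b] & w$freq < bands$high_hz[b]
      colSums(w$psd[sel, , drop = FALSE]) * w$df
    })
    ab <- matrix(ab, ncol = nrow(bands))
    med <- apply(w$psd[in_bb, , drop = FALSE], 2, function(p)
      cumpower_median(w$freq[in_bb], p))
    ent <- sapply(seq_len(nrow(bands)), function(b) {
      sel <- w$freq >= bands$low_hz[b] & w$freq < bands$high_hz[b]
      col_entropy(w$psd[sel, , drop = FALSE])
    })
    ent <- matrix(ent, ncol = nrow(bands))
    ent_bb <- col_entropy(w$psd[in_bb, , drop = FALSE])
    E <- dwt_detail_energies(X, l0 + 2L)
    wrel <- t(E[l0 + (0:2), , drop = FALSE]) / colSums(X^2)
    out[i, ] <- cbind(w$dom_freq, med, ab, ab / total, ent, ent_bb, wrel)
  }
  out
}

col_entropy <- function(P) {
  s <- colSums(P)
  Pn <- sweep(P, 2, pmax(s, .Machine$double.xmin), "/")
  H <- -colSums(ifelse(Pn > 0, Pn * log(Pn), 0)) / log(nrow(P))
  H[s <= 0] <- NA_real_
  H
}

#' Quantile normalization of a feature matrix
#'
#' Rescales each feature to the scale set by its 5% and 95% quantiles,
#' `x' = (x - q05) / (q95 - q05)`, clipping to `[-0.5, 1.5]` to bound
#' outlier influence. Fitting ignores missing rows; a constant feature
#' (q05 == q95) is flagged unusable rather than divided by zero.
#'
#' @param x numeric matrix, epochs x features.
#' @param params optional previously fitted parameters (applies them
#'   deterministically instead of refitting).
#' @return list with `x` (normalized matrix), `params` (list of `q05`,
#'   `q95`, `usable`).
#' @export
quantile_normalize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (is.null(params)) {
    if (sum(stats::complete.cases(x)) < 20)
      stop("need at least 20 non-missing epochs to fit normalization")
    q05 <- apply(x, 2, stats::quantile, probs = 0.05, na.rm = TRUE, names = FALSE)
    q95 <- apply(x, 2, stats::quantile, probs = 0.95, na.rm = TRUE, names = FALSE)
    params <- list(q05 = q05, q95 = q95, usable = (q95 - q05) > 1e-12)
  }
  rng <- params$q95 - params$q05
  rng[!params$usable] <- 1  # avoid 0/0; flagged columns are not to be used
  xn <- sweep(sweep(x, 2, params$q05), 2, rng, "/")
  xn <- pmin(pmax(xn, -0.5), 1.5)
  xn[, !params$usable] <- NA_real_
  list(x = xn, params = params)
}

#' @rdname quantile_normalize
#' @param xn a normalized matrix produced by `quantile_normalize`.
#' @return `quantile_denormalize` returns the matrix on the original scale
#'   (exact only for values that were not clipped).
#' @export
quantile_denormalize <- function(xn, params) {
  rng <- params$q95 - params$q05
  rng[!params$usable] <- 1
  sweep(sweep(as.matrix(xn), 2, rng, "*"), 2, params$q05, "+")
}
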