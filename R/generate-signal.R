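#' Synthesize EEG-like epoch signals from a hypnogram
#'
#' Each non-UNKNOWN epoch receives 30 s of band-limited Gaussian noise
#' shaped, in the frequency domain, to the state's target relative
#' band-power profile plus a broadband noise floor, then scaled to the
#' state's amplitude (with lognormal per-epoch jitter). Spectral shape is
#' therefore a direct, testable function of the generating profile.
#'
#' @param h a [hypnogram()] (or `synthetic_hypnogram`).
#' @param model a [signal_model()].
#' @param seed RNG seed; fixed seed reproduces the segments exactly.
#' @param epochs optional integer subset of epoch indices to synthesize.
#' @return list with `signal` (matrix `samples x epochs`, `NA` columns for
#'   UNKNOWN epochs), `fs` and `epochs` (indices generated).
#' @export
generate_signal <- function(h, model, seed = NULL, epochs = NULL) {
  if (inherits(h, "synthetic_hypnogram")) h <- h$hypnogram
  stopifnot(inherits(model, "signal_model"))
  if (model$amplitude_scale <= 0)
    stop("degenerate signal model: amplitude_scale must be > 0")
  fs <- model$sampling_rate
  n <- round(30 * fs)
  lab <- as.character(h$label)
  if (is.null(epochs)) epochs <- seq_along(lab)
  with_seed(seed, {
    out <- matrix(NA_real_, n, length(epochs))
    freq <- (seq_len(n) - 1) * fs / n
    freq <- pmin(freq, fs - freq)  # two-sided grid folded to [0, fs/2]
    bands <- eeg_bands()
    for (state in rownames(model$band_profiles)) {
      cols <- which(lab[epochs] == state)
      if (!length(cols)) next
      prof <- model$band_profiles[state, ]
      dens <- rep(model$noise_floor / (fs / 2), n)
      for (b in seq_len(nrow(bands))) {
        sel <- freq >= bands$low_hz[b] & freq < bands$high_hz[b]
        dens[sel] <- dens[sel] + prof[b] / (bands$high_hz[b] - bands$low_hz[b])
      }
      mask <- sqrt(dens)
      m <- n %/% 2L
      for (chunk in split(cols, ceiling(seq_along(cols) / 512))) {
        K <- length(chunk)
        # draw the spectrum directly: Hermitian complex Gaussian noise
        Fm <- matrix(0 + 0i, n, K)
        Fm[2:m, ] <- matrix(complex(real = stats::rnorm((m - 1) * K),
                                    imaginary = stats::rnorm((m - 1) * K)),
                            m - 1, K)
        Fm[1, ] <- stats::rnorm(K)
        Fm[m + 1, ] <- stats::rnorm(K)
        Fm[n:(m + 2), ] <- Conj(Fm[2:m, , drop = FALSE])
        S <- Re(stats::mvfft(Fm * mask, inverse = TRUE)) / n
        amp <- model$amplitude_scale * model$state_amplitude[state] *
          stats::rlnorm(K, 0, model$amplitude_jitter_sd)
        sdc <- sqrt(colMeans(S^2))
        out[, chunk] <- S * rep(amp / sdc, each = n)
      }
    }
    list(signal = out, fs = fs, epochs = epochs)
  })
}
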