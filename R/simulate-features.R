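#' Draw per-epoch feature vectors directly from state-specific Gaussians
#'
#' Fast-path simulation for classifier experiments: instead of synthesizing
#' raw signals and extracting spectra, each labelled epoch draws its 21
#' features from a state-specific multivariate Gaussian whose means are
#' derived from the canonical band-power profiles. `separation` scales the
#' between-state mean differences (1 = default profile separation, 0 = all
#' states identical).
#'
#' @param labels stage labels (factor/character vector); UNKNOWN epochs
#'   yield NA rows.
#' @param separation nonnegative scale on between-state mean differences.
#' @param seed RNG seed.
#' @return numeric matrix `length(labels) x 21` with canonical column
#'   names.
#' @export
simulate_features <- function(labels, separation = 1, seed = NULL) {
  lab <- as.character(labels)
  mu <- state_feature_means()
  center <- colMeans(mu)
  sds <- feature_noise_sd()
  with_seed(seed, {
    out <- matrix(NA_real_, length(lab), 21,
                  dimnames = list(NULL, feature_names()))
    for (state in rownames(mu)) {
      idx <- which(lab == state)
      if (!length(idx)) next
      m <- center + separation * (mu[state, ] - center)
      out[idx, ] <- matrix(stats::rnorm(length(idx) * 21, mean = rep(m, each = length(idx)),
                                        sd = rep(sds, each = length(idx))),
                           nrow = length(idx))
    }
    out
  })
}

# Nominal per-state feature means implied by the default signal model.
state_feature_means <- function() {
  prof <- default_band_profiles()
  amp <- c(WAKE = 1.0, N1 = 0.9, N2 = 1.2, N3 = 2.0, REM = 0.8)
  dom <- c(WAKE = 9.5, N1 = 5.5, N2 = 3.5, N3 = 2.0, REM = 5.8)
  med <- c(WAKE = 9.0, N1 = 6.0, N2 = 5.0, N3 = 2.8, REM = 6.3)
  ent_bb <- c(WAKE = 0.92, N1 = 0.90, N2 = 0.85, N3 = 0.72, REM = 0.90)
  states <- rownames(prof)
  mu <- matrix(0, length(states), 21,
               dimnames = list(states, feature_names()))
  for (s in states) {
    rel <- prof[s, ]
    mu[s, ] <- c(dom[s], med[s],
                 10 * amp[s]^2 * rel,            # absolute band powers
                 rel,                            # relative band powers
                 rep(0.8, 5) + 0.1 * (rel - mean(rel)),  # band entropies
                 ent_bb[s],
                 # wavelet detail bands ~8-16, 4-8, 2-4 Hz from the profile
                 0.8 * rel["alpha"] + rel["lowbeta"],
                 rel["theta"],
                 0.6 * rel["delta"])
  }
  mu
}

feature_noise_sd <- function() {
  c(1.2, 1.2, rep(0.8, 5), rep(0.04, 5), rep(0.04, 6), rep(0.04, 3))
}
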