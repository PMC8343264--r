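#' Sleep-architecture parameters for the cohort simulator
#'
#' Describes one patient's habitual sleep: circadian timing of the main sleep
#' period, night duration, napping, the cyclical NREM/REM architecture
#' (cycle durations shrinking across the night, REM proportion growing, deep
#' NREM3 shrinking), intra-sleep arousals (WASO), and recording-quality
#' nuisances (data dropouts, artifact flags).
#'
#' Per-cycle stage proportions are given as a matrix with one row per cycle
#' and columns N1, N2, N3, REM; each row must sum to 1. The default
#' trajectory has REM rising and N3 falling across cycles, the pattern seen
#' in healthy night sleep.
#'
#' @param mean_sleep_onset_clock_time mean sleep-onset clock time, hours of
#'   day in `[0,24)`.
#' @param onset_jitter_sd night-to-night SD of sleep onset, hours.
#' @param night_sleep_duration_mean,night_sleep_duration_sd night sleep
#'   duration distribution, hours.
#' @param nap_rate_per_day expected naps per day (Poisson).
#' @param nap_duration_range min/max nap duration, hours; must stay below the
#'   2-h cutoff that separates naps from main sleep.
#' @param n_cycles number of sleep cycles per night.
#' @param cycle1_duration duration of the first cycle, hours.
#' @param cycle_duration_decay multiplicative factor applied to each
#'   subsequent cycle's duration (strictly in (0,1] for shrinking cycles).
#' @param stage_proportions `n_cycles` x 4 matrix (columns N1,N2,N3,REM),
#'   rows summing to 1.
#' @param sleep_onset_latency hours of NREM lead-in before the first REM
#'   period.
#' @param waso_fraction fraction of sleep-period epochs spent in brief
#'   arousal (wake after sleep onset).
#' @param dropout_rate fraction of epochs lost to recording dropouts.
#' @param artifact_rate fraction of epochs flagged artifactual.
#' @return object of class `sleep_params` (a validated list).
#' @export
sleep_params <- function(mean_sleep_onset_clock_time = 22.5,
                         onset_jitter_sd = 0.75,
                         night_sleep_duration_mean = 9.0,
                         night_sleep_duration_sd = 1.5,
                         nap_rate_per_day = 0.6,
                         nap_duration_range = c(0.3, 1.5),
                         n_cycles = 5,
                         cycle1_duration = 1.9,
                         cycle_duration_decay = 0.85,
                         stage_proportions = default_stage_proportions(n_cycles),
                         sleep_onset_latency = 0.7,
                         waso_fraction = 0.10,
                         dropout_rate = 0.02,
                         artifact_rate = 0.01) {
  p <- list(mean_sleep_onset_clock_time = mean_sleep_onset_clock_time,
            onset_jitter_sd = onset_jitter_sd,
            night_sleep_duration_mean = night_sleep_duration_mean,
            night_sleep_duration_sd = night_sleep_duration_sd,
            nap_rate_per_day = nap_rate_per_day,
            nap_duration_range = nap_duration_range,
            n_cycles = as.integer(n_cycles),
            cycle1_duration = cycle1_duration,
            cycle_duration_decay = cycle_duration_decay,
            stage_proportions = stage_proportions,
            sleep_onset_latency = sleep_onset_latency,
            waso_fraction = waso_fraction,
            dropout_rate = dropout_rate,
            artifact_rate = artifact_rate)
  validate_sleep_params(p)
  class(p) <- "sleep_params"
  p
}

#' @rdname sleep_params
#' @export
default_stage_proportions <- function(n_cycles = 5) {
  base <- matrix(c(
    # N1    N2    N3    REM
    0.10, 0.45, 0.35, 0.10,
    0.10, 0.47, 0.27, 0.16,
    0.11, 0.49, 0.20, 0.20,
    0.12, 0.50, 0.14, 0.24,
    0.13, 0.51, 0.08, 0.28), ncol = 4, byrow = TRUE,
    dimnames = list(NULL, c("N1", "N2", "N3", "REM")))
  if (n_cycles <= 5) return(base[seq_len(n_cycles), , drop = FALSE])
  rbind(base, base[rep(5, n_cycles - 5), , drop = FALSE])
}

validate_sleep_params <- function(p) {
  if (p$n_cycles < 1) stop("need at least one sleep cycle per night")
  sp <- p$stage_proportions
  if (!is.matrix(sp) || ncol(sp) != 4 || nrow(sp) != p$n_cycles)
    stop("stage_proportions must be an n_cycles x 4 matrix (N1,N2,N3,REM)")
  if (any(sp < 0) || any(sp > 1))
    stop("stage proportions must lie in [0, 1]")
  if (any(abs(rowSums(sp) - 1) > 1e-8))
    stop("each row of stage_proportions must sum to 1")
  if (any(p$nap_duration_range >= 2))
    stop("nap durations must be shorter than 2 h (naps by definition)")
  if (p$nap_duration_range[1] <= 0 || diff(p$nap_duration_range) < 0)
    stop("nap_duration_range must be positive and ordered")
  if (p$cycle1_duration <= 0 || p$cycle_duration_decay <= 0)
    stop("cycle durations must be strictly positive")
  for (fr in c("waso_fraction", "dropout_rate", "artifact_rate"))
    if (p[[fr]] < 0 || p[[fr]] >= 1) stop(fr, " must lie in [0, 1)")
  if (p$night_sleep_duration_mean <= 0) stop("night sleep duration must be positive")
  invisible(TRUE)
}

#' Day-level seizure-generating parameters
#'
#' Parameters of the generating model for seizure days: a patient-specific
#' random intercept on the log-odds scale and multiplicative odds effects for
#' days of decreased / increased sleep (relative to baseline days inside the
#' interquartile range). Seizure times within a day are placed into
#' sleep-wake states by relative weights, and seizures feed back on the next
#' day's sleep (longer sleep; degraded quality after a sleep seizure).
#'
#' @param baseline_log_odds mean patient intercept, log-odds of a seizure day
#'   at baseline sleep.
#' @param random_intercept_sd SD of the patient-level intercept.
#' @param or_decreased,or_increased generating odds ratios for the decreased
#'   / increased category relative to baseline (both > 0).
#' @param state_placement_weights named nonnegative weights over
#'   WAKE/N1/N2/N3/REM for placing each seizure's onset state.
#' @param seizure_duration_mean_s,seizure_duration_sd_s lognormal seizure
#'   duration, seconds (mean/sd on the log scale).
#' @param postseizure_effects list with elements `wake_sz` and `sleep_sz`,
#'   each an additive shift on the next day's sleep:
#'   `duration_h`, `waso`, `rem` (proportion shifts).
#' @return object of class `seizure_risk_params`.
#' @export
seizure_risk_params <- function(baseline_log_odds = -1.1,
                                random_intercept_sd = 0.5,
                                or_decreased = 0.92,
                                or_increased = 0.73,
                                state_placement_weights = c(
                                  WAKE = 0.30, N1 = 0.15, N2 = 0.30,
                                  N3 = 0.10, REM = 0.15),
                                seizure_duration_mean_s = 60,
                                seizure_duration_sd_s = 30,
                                postseizure_effects = list(
                                  wake_sz = list(duration_h = 0.5, waso = 0, rem = 0),
                                  sleep_sz = list(duration_h = 1.0, waso = 0.05, rem = -0.05))) {
  if (or_decreased <= 0 || or_increased <= 0)
    stop("generating odds ratios must be > 0")
  if (random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  w <- state_placement_weights
  if (is.null(names(w)) || !all(names(w) %in% STAGE_LEVELS[1:5]))
    stop("state_placement_weights must be named over WAKE/N1/N2/N3/REM")
  if (any(w < 0) || sum(w) <= 0)
    stop("placement weights must be nonnegative and not all zero")
  p <- list(baseline_log_odds = baseline_log_odds,
            random_intercept_sd = random_intercept_sd,
            or_decreased = or_decreased,
            or_increased = or_increased,
            state_placement_weights = w,
            seizure_duration_mean_s = seizure_duration_mean_s,
            seizure_duration_sd_s = seizure_duration_sd_s,
            postseizure_effects = postseizure_effects)
  class(p) <- "seizure_risk_params"
  p
}

#' Per-state spectral model for synthetic EEG-like signals
#'
#' Each sleep-wake state is given a target relative band-power profile over
#' the five canonical bands (delta 1-3, theta 3-7, alpha 7-12, low-beta
#' 12-15, high-beta 15-20 Hz). Signals are synthesized as band-limited
#' Gaussian noise shaped to the profile, with a broadband noise floor and a
#' state-specific amplitude multiplier (deep sleep is high-amplitude, REM
#' low-amplitude).
#'
#' @param sampling_rate Hz; must be at least twice the highest band edge
#'   (>= 40 Hz).
#' @param band_profiles 5 x 5 matrix, rows = states WAKE/N1/N2/N3/REM,
#'   columns = bands delta/theta/alpha/lowbeta/highbeta; nonnegative, rows
#'   summing to 1.
#' @param state_amplitude named amplitude multipliers per state.
#' @param amplitude_scale overall signal scale (arbitrary units); must be
#'   > 0.
#' @param amplitude_jitter_sd lognormal per-epoch amplitude jitter (log-SD).
#' @param noise_floor relative broadband noise power added outside the
#'   shaped bands.
#' @return object of class `signal_model`.
#' @export
signal_model <- function(sampling_rate = 128,
                         band_profiles = default_band_profiles(),
                         state_amplitude = c(WAKE = 1.0, N1 = 0.9, N2 = 1.2,
                                             N3 = 2.0, REM = 0.8),
                         amplitude_scale = 50,
                         amplitude_jitter_sd = 0.15,
                         noise_floor = 0.05) {
  if (sampling_rate < 40)
    stop("sampling_rate must be at least twice the highest band edge (>= 40 Hz)")
  if (!is.matrix(band_profiles) || nrow(band_profiles) != 5 || ncol(band_profiles) != 5)
    stop("band_profiles must be a 5x5 matrix (states x bands)")
  if (any(band_profiles < 0)) stop("band-power profiles must be nonnegative")
  if (amplitude_scale <= 0)
    stop("degenerate signal model: amplitude_scale must be > 0")
  m <- list(sampling_rate = sampling_rate,
            band_profiles = band_profiles,
            state_amplitude = state_amplitude,
            amplitude_scale = amplitude_scale,
            amplitude_jitter_sd = amplitude_jitter_sd,
            noise_floor = noise_floor)
  class(m) <- "signal_model"
  m
}

#' @rdname signal_model
#' @export
default_band_profiles <- function() {
  matrix(c(
    # delta theta alpha lowbeta highbeta
    0.15, 0.20, 0.35, 0.15, 0.15,  # WAKE: alpha-dominant
    0.25, 0.35, 0.20, 0.10, 0.10,  # N1: theta
    0.40, 0.20, 0.15, 0.18, 0.07,  # N2: delta + spindle-band
    0.70, 0.15, 0.08, 0.04, 0.03,  # N3: slow-wave delta
    0.20, 0.40, 0.20, 0.10, 0.10), # REM: mixed theta, low amplitude
    ncol = 5, byrow = TRUE,
    dimnames = list(c("WAKE", "N1", "N2", "N3", "REM"),
                    c("delta", "theta", "alpha", "lowbeta", "highbeta")))
}
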