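---
title: "Methods: sleep–seizure interaction analysis on synthetic ambulatory EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep–seizure interaction analysis on synthetic ambulatory EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnorisk)
```

This vignette documents the statistical models, the synthetic-cohort
generator, and the numerical choices behind `somnorisk`. The package
mirrors the analysis chain used in long-term ambulatory intracranial EEG
studies of sleep and seizure risk, where months of continuous recording
per patient are staged semi-automatically and day-level sleep variables
are related to subsequent seizure occurrence.

## 1. Conventions

* **Epoch**: the 30-second scoring unit. All hypnograms are contiguous
  30-s label series over `WAKE, N1, N2, N3, REM, UNKNOWN`.
* **Day boundary**: days run **noon to noon** so that a full night of
  sleep belongs to a single day key (`day_key()`); the day labelled
  `2020-01-01` spans 2020-01-01 12:00 to 2020-01-02 12:00 UTC.
* **Nap**: any sleep period shorter than 2 hours.
* **WASO** (wake after sleep onset): wake epochs inside a sleep period;
  counted as part of total sleep duration.
* **48-h outcome window**: the outcome for a categorized day is 1 if any
  seizure onset falls in the half-open interval `(day end, day end + 48 h]`
  — the window starts at the *end* of the day's 24-h measurement window.
  Whether the original analyses also counted seizures inside the
  categorized day itself is ambiguous in the literature; starting at the
  day's end is the stricter, implemented reading.

## 2. The seizure-risk model

`fit_mixed_logit()` fits, for patient $i$ and day $t$,

$$\operatorname{logit} P(y_{it}=1) = \mathbf{x}_{it}'\boldsymbol\beta + u_i,
\qquad u_i \sim N(0, \sigma^2),$$

typically with $\mathbf{x}_{it}$ encoding the day's sleep category
(baseline / decreased / increased). The marginal likelihood integrates
$u_i$ out per patient by **adaptive Gauss–Hermite quadrature**: a Newton
step finds each patient's posterior mode, the 15-node Hermite rule is
recentred and rescaled there, and $(\boldsymbol\beta, \log\sigma)$ is
maximized by BFGS. Standard errors come from the numerically
differentiated Hessian at the optimum; effects are reported as odds
ratios with Wald intervals, and `risk_or_table()` flags significance at a
Bonferroni-corrected level (0.025 for the usual two contrasts per sleep
variable).

Implementation choices worth knowing:

* Rows are collapsed to weighted `(patient, covariate pattern, outcome)`
  cells before fitting, which makes a 10-patient × 430-day fit take a
  fraction of a second without changing the likelihood.
* With `sigma = 0` the quadrature collapses and the model is *exactly*
  ordinary logistic regression; with one binary predictor the estimate is
  the closed-form 2×2-table odds ratio. The test suite uses this, plus an
  `lme4::glmer(nAGQ = 15)` cross-check, as oracles.
* Extreme coefficients or standard errors trigger a complete-separation
  warning rather than silent nonsense.

Category labels come from `categorize_days()`: per patient, the 25th and
75th percentiles of the sleep variable are computed on **seizure-free
days only** (quantile type 7); days below/above are `decreased` /
`increased`, seizure days are `excluded` and never move the thresholds.
When several variables are analysed, each is categorized marginally.

Post-seizure comparisons (`rm_anova_postseizure()`) classify days as
control / wake-seizure / sleep-seizure — days with both kinds are
excluded — and compare per-patient condition means with a
repeated-measures ANOVA using the **Greenhouse–Geisser** epsilon (closed
form from the double-centred covariance, bounded in $[1/(k-1), 1]$) and
**Dunnett** many-to-one contrasts via the equicorrelated ($\rho = 0.5$)
multivariate $t$ distribution. Proportions are arcsine-square-root
transformed first (`bounded = TRUE`). At $k = 2$ the Dunnett test reduces
exactly to the paired $t$-test, another tested oracle.

## 3. The synthetic cohort generator

`generate_hypnogram()` builds each night as a short NREM lead-in followed
by `n_cycles` cycles, **each cycle beginning with its REM period**. This
makes the literal cycle definition used downstream — REM-period start to
next REM-period start — recover the generating cycle boundaries exactly,
so cycle analytics can be validated against truth. Defaults
(`sleep_params()`):

| parameter | default | rationale |
|---|---|---|
| sleep onset | 22:30 ± 0.75 h | habitual adult bedtime with night-to-night jitter |
| night duration | 9.0 ± 1.5 h | long in-bed durations seen in ambulatory epilepsy cohorts |
| cycles / night | 5, first 1.9 h, decay 0.85 | cycles shorten across the night |
| stage mix / cycle | REM 0.10 → 0.28, N3 0.35 → 0.08 | REM share rises, deep sleep falls |
| WASO fraction | 0.10 | brief arousals sprinkled inside sleep (endpoints and cycle REM onsets protected) |
| naps | Poisson(0.6)/day, 0.3–1.5 h, 13:00–18:00 | kept < 2 h by construction, ≥ 30 min of wake insulation |
| dropouts / artifacts | 2% / 1% of epochs | recording-quality nuisances feeding the pruning rules |

Seizure days (`generate_seizures()`, `make_cohort()`) follow the same
random-intercept logistic form the fitting function assumes, with
baseline log-odds −1.1 (≈ 25% seizure-day probability), intercept SD 0.5,
and configurable generating odds ratios. Seizure onsets are placed into
epochs of a drawn sleep-wake state; seizures feed back on the next night
(longer sleep; after sleep seizures also more WASO and less REM), giving
the post-seizure analytics a real signal to find. `make_cohort()` draws
per-patient day counts from 224–709 days, the scale of published
ambulatory cohorts.

**What the generator does *not* emulate**: circadian/multiday seizure
cycles, medication effects, stage-transition dynamics within NREM beyond
the per-cycle proportions, inter-channel structure (signals are single
channel), and any reverse-causal pathway other than the scripted
post-seizure feedback.

## 4. Signals and features

`generate_signal()` synthesizes each epoch as Gaussian noise shaped in
the frequency domain to the state's relative band-power profile
(`signal_model()`; delta-dominant N3 at high amplitude, mixed-frequency
low-amplitude REM, alpha-dominant wake) plus a 5% broadband noise floor,
with lognormal per-epoch amplitude jitter. The spectrum is drawn directly
as Hermitian complex Gaussian noise and inverse-FFT'd once per chunk,
which is exactly equivalent in distribution to filtering white noise but
roughly twice as fast.

`extract_features()` computes the canonical 21 features per epoch:

* **Welch PSD**: 4-s periodic Hann windows, 50% overlap, one-sided
  density. Band edges are half-open `[low, high)` over delta 1–3, theta
  3–7, alpha 7–12, low-beta 12–15, high-beta 15–20 Hz, with 1–25 Hz as
  the broadband reference; relative powers therefore sum to < 1.
* **Mean dominant frequency** averages the 1–25 Hz peak over Welch
  windows; **spectral median frequency** interpolates the cumulative
  power linearly within the crossing bin, so a pure tone on the 0.25-Hz
  grid is recovered to within one bin.
* **Spectral entropies** (five bands + broadband) are Shannon entropies
  of the within-band normalized PSD divided by `log(nbins)`, so they lie
  in [0, 1]. Note a *leakage floor*: a pure tone scores ≈ 0.29 rather
  than 0 because the Hann taper spreads power into neighbouring bins; the
  exact 0/1 limits hold for analytic spectra and are tested there.
* **Wavelet energies**: relative energies of three db4 DWT detail levels
  covering ≈ 8–16, 4–8 and 2–4 Hz (periodic pyramid). The sampling rate
  must place 16 Hz on a dyadic edge (`fs = 16·2^m`, e.g. 64 or 128 Hz).

Quantile normalization rescales features by their 5%/95% quantiles and
clips to [−0.5, 1.5]; constant features are flagged unusable rather than
divided by zero.

## 5. Staging and pruning

`train_stager()` reproduces the semi-automated protocol: 9 training days
chosen at equidistant positions among usable days
(`select_training_days()`), greedy sequential forward selection of 8 of
the 21 features by cross-validated macro recall, then model selection
over Gaussian naive Bayes and KNN ($K = 3\ldots50$), each on raw and
quantile-normalized features. Ties prefer simpler models (naive Bayes,
then smaller $K$). N1 is the hardest class, as in manual scoring; no
guarantee is made about its recall, and end-to-end accuracy checks use
the WAKE/N2/N3/REM macro average.

Pruning (`pruning_rules()`): epochs with > 50% missing samples (or
artifact flags) become `UNKNOWN`; noon-to-noon days with > 30% `UNKNOWN`
epochs are excluded from all analyses. Isolated runs of pure N1 far from
substantive sleep are ignored by `detect_sleep_periods()`; wake gaps
shorter than 30 minutes stay inside a sleep period as WASO.

## 6. Reproducibility and problem sizes

Every stochastic function takes a `seed` and restores the global RNG
state afterwards; sub-seeds are derived deterministically, so whole
pipelines are reproducible from one integer. `scripts/acceptance.R`
re-derives the headline percent-change-in-odds figures from 40 replicate
cohorts of 10 patients × 430 days per variable set (a few minutes on one
CPU); at that size a single replicate's log-odds-ratio noise is ≈ 0.08,
and the 40-replicate mean recovers generating odds ratios to well within
±0.05. The end-to-end staging test runs 2 patients × 20 days of full
128-Hz signal synthesis (~5 minutes); larger cohorts scale linearly and
are embarrassingly parallel across patients.

## 7. Limitations

The generator's architecture is stylized (proportions, not transition
dynamics), the risk model matches the generating family (so recovery
tests validate the estimator, not the model's adequacy for real data),
and the association between sleep categories and next-48-h seizures is
correlational by construction — as in the motivating studies, where
reverse causality between disturbed sleep and impending seizures cannot
be excluded.
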