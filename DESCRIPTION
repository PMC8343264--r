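Package: somnorisk
Title: Long-Term Sleep Staging and Seizure-Risk Modelling from Continuous EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the interaction between sleep and epileptic
    seizures in long-term (months to years) continuous EEG recordings.
    Includes a synthetic-cohort simulator with known ground truth
    (cyclical sleep architecture, naps, arousals, dropouts, and day-level
    seizure generation from a random-intercept logistic model), per-epoch
    spectral/entropy/wavelet feature extraction, patient-specific
    semi-automated sleep staging (sequential feature selection, KNN or
    naive Bayes, pruning rules), hypnogram analytics (sleep periods, naps,
    WASO, sleep cycles, circadian histograms), day-level interquartile
    categorization of sleep variables with 48-hour seizure outcome windows,
    a random-intercept logistic regression fitted by adaptive Gauss-Hermite
    quadrature, repeated-measures ANOVA with Greenhouse-Geisser correction
    and Dunnett contrasts, and bootstrap difference-of-means intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    mvtnorm
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
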