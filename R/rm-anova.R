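#' Greenhouse-Geisser epsilon from a repeated-measures covariance matrix
#'
#' Computed from the covariance of the within-subject conditions via the
#' double-centred matrix; bounded in `[1/(k-1), 1]`.
#'
#' @param S k x k sample covariance matrix of the condition columns.
#' @return epsilon estimate.
#' @export
gg_epsilon <- function(S) {
  k <- nrow(S)
  J <- diag(k) - 1 / k
  Sc <- J %*% S %*% J
  eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  min(max(eps, 1 / (k - 1)), 1)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Subjects in rows, conditions in columns. Sphericity is not assumed: the
#' F test's degrees of freedom are multiplied by the Greenhouse-Geisser
#' epsilon. Bounded data (proportions) should be arcsine-square-root
#' transformed first (`bounded = TRUE`).
#'
#' @param x numeric matrix `subjects x conditions` (complete cases only are
#'   used).
#' @param bounded transform entries by `asin(sqrt(x))` before the ANOVA.
#' @return list with `F`, `df1`, `df2` (corrected), `epsilon`, `p_value`,
#'   `mse` (error mean square) and `n` (subjects used).
#' @export
rm_anova <- function(x, bounded = FALSE) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects with all conditions")
  if (bounded) {
    if (any(x < 0 | x > 1)) stop("bounded data must lie in [0, 1]")
    x <- asin(sqrt(x))
  }
  grand <- mean(x)
  cond_means <- colMeans(x)
  subj_means <- rowMeans(x)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- sum((x - outer(subj_means, cond_means, `+`) + grand)^2)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df1
  mse <- ss_err / df2
  eps <- gg_epsilon(stats::cov(x))
  Fv <- if (ms_cond == 0) 0 else ms_cond / mse
  p <- if (mse == 0 && ms_cond == 0) 1 else
    stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  list(F = Fv, df1 = df1 * eps, df2 = df2 * eps, epsilon = eps,
       p_value = p, mse = mse, n = n, transformed = bounded)
}

#' Dunnett many-to-one comparisons for repeated measures
#'
#' Compares each condition against the control using the repeated-measures
#' error mean square; two-sided p-values come from the equicorrelated
#' (rho = 0.5) multivariate t distribution.
#'
#' @param x numeric matrix `subjects x conditions`; complete cases used.
#' @param control index or name of the control column (default 1).
#' @param bounded arcsine-square-root transform first.
#' @return data.frame with `condition`, `estimate` (mean difference vs
#'   control on the analysis scale), `t`, `p_value` (Dunnett-adjusted).
#' @export
dunnett_vs_control <- function(x, control = 1, bounded = FALSE) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (is.character(control)) control <- match(control, colnames(x))
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("need at least 3 subjects with all conditions")
  if (bounded) {
    if (any(x < 0 | x > 1)) stop("bounded data must lie in [0, 1]")
    x <- asin(sqrt(x))
  }
  a <- rm_anova(x)
  others <- setdiff(seq_len(k), control)
  est <- colMeans(x)[others] - mean(x[, control])
  se <- sqrt(2 * a$mse / n)
  tval <- est / se
  df <- (k - 1) * (n - 1)
  m <- length(others)
  corr <- matrix(0.5, m, m); diag(corr) <- 1
  p <- vapply(tval, function(t0) {
    1 - mvtnorm::pmvt(lower = rep(-abs(t0), m), upper = rep(abs(t0), m),
                      df = df, corr = corr)[1]
  }, 0)
  data.frame(condition = colnames(x)[others] %||% paste0("cond", others),
             estimate = unname(est), t = unname(tval), p_value = unname(p))
}

#' Post-seizure repeated-measures comparison
#'
#' Convenience wrapper for the control / wake-seizure / sleep-seizure
#' analysis: takes per-patient condition means of a sleep variable, runs
#' the Greenhouse-Geisser-corrected repeated-measures ANOVA (arcsine
#' transforming proportions) and Dunnett's comparisons against control.
#'
#' @param x matrix `patients x conditions` with the control condition in
#'   column 1 (patients missing any condition are dropped listwise).
#' @param bounded TRUE for proportion variables.
#' @return list with `anova` ([rm_anova()] output) and `dunnett`
#'   ([dunnett_vs_control()] output).
#' @export
rm_anova_postseizure <- function(x, bounded = FALSE) {
  list(anova = rm_anova(x, bounded = bounded),
       dunnett = dunnett_vs_control(x, control = 1, bounded = bounded))
}

#' Bootstrap difference-of-means distribution
#'
#' Resamples each group with replacement, recording the difference of group
#' means (A minus B), with a 95% percentile confidence interval.
#'
#' @param a,b numeric samples (nonempty).
#' @param n_boot bootstrap draws (default 10000; fewer than 100 warns).
#' @param seed RNG seed; fixed seed reproduces the distribution.
#' @param conf_level CI level (default 0.95).
#' @return list with `diff` (observed difference), `boot` (vector of
#'   resampled differences), `ci` (percentile interval).
#' @export
bootstrap_mean_difference <- function(a, b, n_boot = 10000, seed = NULL,
                                      conf_level = 0.95) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals")
  with_seed(seed, {
    boot <- replicate(n_boot,
                      mean(sample(a, replace = TRUE)) -
                        mean(sample(b, replace = TRUE)))
    alpha <- (1 - conf_level) / 2
    list(diff = mean(a) - mean(b), boot = boot,
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))))
  })
}
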