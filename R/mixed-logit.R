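#' Random-intercept logistic regression by adaptive Gauss-Hermite quadrature
#'
#' Fits the day-level seizure-risk model: a logistic regression for a binary
#' outcome with fixed effects (typically the sleep category: decreased /
#' baseline / increased) and a patient-specific random intercept
#' `u_i ~ N(0, sigma^2)`. The marginal likelihood integrates the random
#' intercept out per patient with adaptive Gauss-Hermite quadrature
#' (quadrature recentred at each patient's posterior mode, `nAGQ` nodes) and
#' is maximized over the fixed effects and `sigma`. Inference on the fixed
#' effects is Wald, reported as odds ratios with 95% confidence intervals.
#'
#' With `sigma` fixed at 0 the model reduces exactly to ordinary logistic
#' regression (no quadrature error), so a single binary predictor recovers
#' the closed-form 2x2-table odds ratio.
#'
#' @param formula model formula, e.g. `outcome ~ category`.
#' @param data data frame containing the variables and the grouping column.
#' @param group name of the grouping (patient id) column.
#' @param nAGQ number of quadrature nodes (default 15).
#' @param sigma if non-NULL, the random-intercept SD is fixed at this value
#'   (0 gives plain logistic regression); otherwise estimated.
#' @param conf_level confidence level for Wald intervals (default 0.95).
#' @return object of class `mixed_logit` with `print`, `summary`, `coef`,
#'   `vcov`, `confint`, `predict`, `simulate`, `residuals`, `logLik` and
#'   `plot` methods.
#' @examples
#' d <- simulate_category_days(4, 100, seed = 1)
#' d$y <- generate_seizures(d, seizure_risk_params(), seed = 2)$seizure_day
#' fit <- fit_mixed_logit(y ~ category, d, group = "patient")
#' summary(fit)
#' @export
fit_mixed_logit <- function(formula, data, group, nAGQ = 15, sigma = NULL,
                            conf_level = 0.95) {
  stopifnot(nAGQ >= 1)
  if (is.null(data[[group]])) stop("grouping column '", group, "' not found")
  dd <- data[, unique(c(all.vars(formula), group)), drop = FALSE]
  keep <- stats::complete.cases(dd)
  dd <- dd[keep, , drop = FALSE]
  mf <- stats::model.frame(formula, dd, na.action = NULL)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  gid <- factor(dd[[group]])

  # collapse duplicated (group, X-row, y) cells into weighted rows
  key <- paste(gid, apply(X, 1, paste, collapse = "\r"), y, sep = "\r")
  first <- !duplicated(key)
  w <- as.vector(table(key)[key[first]])
  Xc <- X[first, , drop = FALSE]
  yc <- y[first]
  gc <- gid[first]
  groups <- split(seq_along(yc), gc)

  gh <- gauss_hermite(nAGQ)
  p <- ncol(Xc)

  loglik_parts <- function(beta, sg, return_modes = FALSE) {
    eta0 <- drop(Xc %*% beta)
    ll <- 0
    modes <- numeric(length(groups))
    for (j in seq_along(groups)) {
      ii <- groups[[j]]
      ll_i <- group_loglik(eta0[ii], yc[ii], w[ii], sg, gh)
      ll <- ll + ll_i$logL
      modes[j] <- ll_i$mode
    }
    if (return_modes) list(ll = ll, modes = modes) else ll
  }

  # start from the plain logistic fit
  glm0 <- stats::glm.fit(Xc, yc, weights = w, family = stats::binomial())
  beta0 <- glm0$coefficients
  beta0[!is.finite(beta0)] <- 0

  if (!is.null(sigma)) {
    negll <- function(par) -loglik_parts(par, sigma)
    opt <- stats::optim(beta0, negll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    est <- opt$par
    sig_hat <- sigma
    H <- stats::optimHess(est, negll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
    vcov_beta <- V
    conv <- opt$convergence == 0
    ll <- -opt$value
  } else {
    negll <- function(par) -loglik_parts(par[seq_len(p)], exp(par[p + 1]))
    opt <- stats::optim(c(beta0, log(0.3)), negll, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12))
    est <- opt$par[seq_len(p)]
    sig_hat <- unname(exp(opt$par[p + 1]))
    H <- stats::optimHess(opt$par, negll)
    V <- tryCatch(solve(H), error = function(e) matrix(NA, p + 1, p + 1))
    vcov_beta <- V[seq_len(p), seq_len(p), drop = FALSE]
    conv <- opt$convergence == 0
    ll <- -opt$value
  }
  names(est) <- colnames(Xc)
  dimnames(vcov_beta) <- list(colnames(Xc), colnames(Xc))

  se <- sqrt(pmax(diag(vcov_beta), 0))
  separation <- any(abs(est) > 15 | se > 10, na.rm = TRUE)
  if (separation)
    warning("possible complete separation: extreme coefficient or SE")

  modes <- loglik_parts(est, sig_hat, return_modes = TRUE)$modes
  names(modes) <- names(groups)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  keep <- colnames(Xc) != "(Intercept)"
  or_table <- data.frame(
    term = colnames(Xc)[keep],
    odds_ratio = exp(est[keep]),
    ci_low = exp(est[keep] - z * se[keep]),
    ci_high = exp(est[keep] + z * se[keep]),
    p_value = 2 * stats::pnorm(-abs(est[keep] / se[keep])),
    row.names = NULL)

  out <- list(coefficients = est, sigma = sig_hat,
              sigma_fixed = !is.null(sigma),
              vcov = vcov_beta, logLik = ll, nobs = length(y),
              ngroups = length(groups), nAGQ = nAGQ,
              converged = conv, separation = separation,
              or_table = or_table, conf_level = conf_level,
              ranef = modes,
              formula = formula, group = group,
              terms = attr(mf, "terms"),
              xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
              call = match.call())
  class(out) <- "mixed_logit"
  out
}

# Marginal log-likelihood contribution of one group via AGQ.
# eta0: fixed-effect linear predictor; y, w: outcome and cell weights.
group_loglik <- function(eta0, y, w, sg, gh) {
  cond <- function(u) sum(w * (y * (eta0 + u) - log1p(exp(eta0 + u))))
  if (sg <= 0) return(list(logL = cond(0), mode = 0))
  h <- function(u) cond(u) - u^2 / (2 * sg^2)
  # Newton for the posterior mode
  u <- 0
  for (it in 1:25) {
    pr <- stats::plogis(eta0 + u)
    g1 <- sum(w * (y - pr)) - u / sg^2
    g2 <- -sum(w * pr * (1 - pr)) - 1 / sg^2
    step <- g1 / g2
    u <- u - step
    if (abs(step) < 1e-10) break
  }
  pr <- stats::plogis(eta0 + u)
  s <- 1 / sqrt(sum(w * pr * (1 - pr)) + 1 / sg^2)
  uk <- u + sqrt(2) * s * gh$nodes
  lk <- log(gh$weights) + gh$nodes^2 + vapply(uk, h, 0)
  m <- max(lk)
  # prior normalisation: -log(sg * sqrt(2*pi)) from the N(0, sg^2) density
  logL <- log(sqrt(2) * s) + m + log(sum(exp(lk - m))) -
    log(sg) - 0.5 * log(2 * pi)
  list(logL = logL, mode = u)
}

#' @export
print.mixed_logit <- function(x, ...) {
  cat("Random-intercept logistic regression (adaptive Gauss-Hermite,",
      x$nAGQ, "nodes)\n")
  cat("  groups:", x$ngroups, " observations:", x$nobs, "\n")
  cat(sprintf("  random-intercept SD: %.4f%s\n", x$sigma,
              if (x$sigma_fixed) " (fixed)" else ""))
  print(format(x$or_table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mixed_logit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `z value` = object$coefficients / se,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(object$coefficients / se)))
  structure(list(coefficients = coefs, or_table = object$or_table,
                 sigma = object$sigma, logLik = object$logLik,
                 ngroups = object$ngroups, nobs = object$nobs,
                 converged = object$converged, call = object$call),
            class = "summary.mixed_logit")
}

#' @export
print.summary.mixed_logit <- function(x, ...) {
  cat("Call: "); print(x$call)
  cat("\nFixed effects (log-odds scale):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("\nOdds ratios:\n")
  print(format(x$or_table, digits = 3), row.names = FALSE)
  cat(sprintf("\nRandom-intercept SD %.4f; log-likelihood %.2f (%d groups, %d obs)\n",
              x$sigma, x$logLik, x$ngroups, x$nobs))
  invisible(x)
}

#' @export
coef.mixed_logit <- function(object, ...) object$coefficients

#' @export
vcov.mixed_logit <- function(object, ...) object$vcov

#' @export
logLik.mixed_logit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              !object$sigma_fixed, class = "logLik")
}

#' @export
confint.mixed_logit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.mixed_logit <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                  xlev = object$xlevels))
  eta <- drop(X %*% object$coefficients)  # conditional on u = 0
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.mixed_logit <- function(object, data = NULL,
                                  type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  if (is.null(data)) stop("supply the fitting data to compute residuals")
  dd <- data[, unique(c(all.vars(object$formula), object$group)),
             drop = FALSE]
  dd <- dd[stats::complete.cases(dd), , drop = FALSE]
  mf <- stats::model.frame(object$formula, dd, na.action = NULL)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(object$terms, mf)
  u <- object$ranef[as.character(dd[[object$group]])]
  p <- stats::plogis(drop(X %*% object$coefficients) + u)
  if (type == "response") y - p else (y - p) / sqrt(p * (1 - p))
}

#' @export
simulate.mixed_logit <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, ...) {
  if (is.null(newdata)) stop("supply newdata with predictors and the group column")
  with_seed(seed, {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    xlev = object$xlevels))
    g <- factor(newdata[[object$group]])
    out <- replicate(nsim, {
      u <- stats::rnorm(nlevels(g), 0, object$sigma)[as.integer(g)]
      stats::rbinom(nrow(X), 1, stats::plogis(drop(X %*% object$coefficients) + u))
    })
    as.data.frame(out)
  })
}

#' @export
plot.mixed_logit <- function(x, ...) {
  ot <- x$or_table
  n <- nrow(ot)
  graphics::plot(ot$odds_ratio, seq_len(n), xlim = range(c(ot$ci_low, ot$ci_high, 1)),
                 ylim = c(0.5, n + 0.5), yaxt = "n", log = "x",
                 xlab = "odds ratio (log scale)", ylab = "", pch = 19, ...)
  graphics::segments(ot$ci_low, seq_len(n), ot$ci_high, seq_len(n))
  graphics::abline(v = 1, lty = 2)
  graphics::axis(2, at = seq_len(n), labels = ot$term, las = 1)
  invisible(x)
}

#' Odds-ratio table of a fitted seizure-risk model
#'
#' @param fit a [fit_mixed_logit()] object.
#' @param bonferroni_alpha corrected significance level reported alongside
#'   (default 0.025, two contrasts per variable).
#' @return data.frame with term, odds ratio, CI, p-value and significance
#'   at the corrected level.
#' @export
risk_or_table <- function(fit, bonferroni_alpha = 0.025) {
  ot <- fit$or_table
  ot$significant <- ot$p_value < bonferroni_alpha
  ot
}
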