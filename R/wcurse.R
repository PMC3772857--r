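# Winner's-curse adjustment of significance-selected effect estimates:
# conditional maximum likelihood given that the discovery estimate crossed
# the genome-wide significance threshold, plus the combined (weighted)
# estimator.

#' Describe a discovery-stage effect estimate
#'
#' @param beta_hat Signed log odds ratio from the discovery scan.
#' @param se Positive standard error of `beta_hat`.
#' @param alpha Two-sided discovery significance threshold; default 5e-8
#'   (genome-wide significance). The implied critical value is
#'   `c = qnorm(1 - alpha/2)`.
#' @return List of class `discovery_estimate`. Errors unless
#'   `|beta_hat|/se >= c` (the estimate must actually have been selected).
#' @export
discovery_estimate <- function(beta_hat, se, alpha = 5e-8) {
  if (!is.finite(beta_hat)) stop("beta_hat must be finite", call. = FALSE)
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  cval <- stats::qnorm(1 - alpha / 2)
  if (abs(beta_hat) / se < cval) {
    stop(sprintf(
      "estimate is not significant at alpha = %g (|z| = %.3f < c = %.3f); ",
      alpha, abs(beta_hat) / se, cval),
      "the winner's-curse correction conditions on selection", call. = FALSE)
  }
  structure(list(beta_hat = beta_hat, se = se, alpha = alpha, c = cval),
            class = "discovery_estimate")
}

# conditional log-likelihood of observing beta_hat given |beta_hat/se| > c,
# as a function of the true beta (all on the |beta_hat| > 0 side)
.wc_cloglik <- function(beta, beta_hat, se, cval) {
  stats::dnorm((beta_hat - beta) / se, log = TRUE) -
    log(stats::pnorm(-cval + beta / se) + stats::pnorm(-cval - beta / se))
}

#' Conditional-MLE winner's-curse correction
#'
#' Maximizes the density of the observed estimate conditional on having
#' crossed the significance threshold,
#' `phi((b^ - b)/se) / [Phi(-c + b/se) + Phi(-c - b/se)]`,
#' over the true log OR `b`. Selection on magnitude biases the naive
#' estimate away from zero, so the maximizer lies between 0 and `beta_hat`;
#' as `|beta_hat|/se` grows the conditioning event approaches probability 1
#' and the correction vanishes.
#'
#' @param est A [discovery_estimate()], or a numeric `beta_hat` (then `se`
#'   and `alpha` must be given).
#' @param se,alpha Used only when `est` is numeric.
#' @return The adjusted log OR (same sign as `beta_hat`).
#' @export
conditional_mle <- function(est, se = NULL, alpha = 5e-8) {
  if (!inherits(est, "discovery_estimate")) {
    est <- discovery_estimate(est, se, alpha)
  }
  s <- sign(est$beta_hat)
  bh <- abs(est$beta_hat)
  opt <- stats::optimize(.wc_cloglik, interval = c(0, bh), maximum = TRUE,
                         beta_hat = bh, se = est$se, cval = est$c,
                         tol = 1e-10)
  s * opt$maximum
}

#' Full winner's-curse adjustment of a discovery estimate
#'
#' Reports the naive estimate, the conditional MLE, and the combined
#' (weighted) estimator `weight * naive + (1 - weight) * conditional MLE`.
#' The conditional MLE tends to overcorrect for estimates near the
#' threshold; the combined estimator splits the difference and is the value
#' used downstream (default weight 0.5; the weighting is exposed because the
#' cited correction leaves it a method parameter).
#'
#' @inheritParams conditional_mle
#' @param weight Weight on the naive estimate in the combined estimator,
#'   in [0, 1]; default 0.5.
#' @return List of class `wc_adjustment`: `naive`, `conditional`,
#'   `combined`, `use` (the downstream choice, `"combined"`), `weight`,
#'   `alpha`, and the inflation factor (%) of the naive estimate relative to
#'   the combined one.
#' @export
wc_adjust <- function(est, se = NULL, alpha = 5e-8, weight = 0.5) {
  if (!inherits(est, "discovery_estimate")) {
    est <- discovery_estimate(est, se, alpha)
  }
  stopifnot(weight >= 0, weight <= 1)
  cmle <- conditional_mle(est)
  combined <- weight * est$beta_hat + (1 - weight) * cmle
  structure(list(
    naive = est$beta_hat, conditional = cmle, combined = combined,
    use = "combined", weight = weight, alpha = est$alpha,
    inflation_pct = if (combined != 0) inflation_factor(est$beta_hat, combined)
                    else 0
  ), class = "wc_adjustment")
}

#' @export
print.wc_adjustment <- function(x, ...) {
  cat(sprintf(
    "winner's-curse adjustment (alpha %.3g, weight %.2f on naive):\n  naive %.5f (OR %.4f)\n  conditional MLE %.5f (OR %.4f)\n  combined %.5f (OR %.4f)  <- used downstream\n  inflation of naive vs combined: %.2f%%\n",
    x$alpha, x$weight, x$naive, exp(x$naive), x$conditional,
    exp(x$conditional), x$combined, exp(x$combined), x$inflation_pct))
  invisible(x)
}

#' Inflation factor of a naive estimate over its adjusted value
#'
#' `100 * (beta_hat - beta_adjusted) / beta_adjusted`, the percentage by
#' which the selected estimate overstates the adjusted one.
#'
#' @param beta_hat Naive log OR.
#' @param beta_adjusted Adjusted log OR; must have the same sign as
#'   `beta_hat` and magnitude no larger.
#' @return Percentage (>= 0).
#' @export
inflation_factor <- function(beta_hat, beta_adjusted) {
  if (beta_adjusted == 0) stop("adjusted estimate is zero; inflation undefined",
                               call. = FALSE)
  if (sign(beta_hat) != sign(beta_adjusted)) {
    stop("beta_hat and beta_adjusted must have the same sign", call. = FALSE)
  }
  if (abs(beta_adjusted) > abs(beta_hat)) {
    stop("beta_adjusted must not exceed beta_hat in magnitude", call. = FALSE)
  }
  100 * (beta_hat - beta_adjusted) / beta_adjusted
}

#' Standard error back-derived from a published confidence interval
#'
#' `se = (log(upper) - log(lower)) / (2 * qnorm(0.975))` for an odds ratio
#' with a symmetric Wald CI on the log scale. A documented utility for
#' demonstrating the winner's-curse adjustment on published odds ratios
#' whose discovery-stage standard errors are not printed.
#'
#' @param ci_low,ci_high Confidence limits of the odds ratio.
#' @return Standard error of the log odds ratio.
#' @export
se_from_ci <- function(ci_low, ci_high) {
  stopifnot(ci_low > 0, ci_high > ci_low)
  (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
}
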