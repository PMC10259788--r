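#' Watson's U-squared statistic for a wrapped Cauchy hypothesis
#'
#' Computes the rotation-invariant Cramer-von-Mises-type statistic
#' \deqn{U^2 = \sum_i \left(u_{(i)} - \frac{2i-1}{2n}\right)^2
#'   - n\,(\bar u - 1/2)^2 + \frac{1}{12 n}}
#' where `u_(i)` are the sorted probability-integral transforms of the
#' sample under the hypothesized wrapped Cauchy distribution (arc-length
#' CDF from the antimode). Because the statistic subtracts the centred
#' term, it does not depend on the CDF anchor: rotating the data and `mu`
#' together leaves it unchanged.
#'
#' @param theta numeric vector of angles in radians, length at least 2.
#' @param mu,rho hypothesized wrapped Cauchy parameters.
#' @return the U-squared value (nonnegative).
#' @export
watson_u2 <- function(theta, mu, rho) {
  theta <- as_angles(theta)
  n <- length(theta)
  if (n < 2L) stop("need at least 2 angles", call. = FALSE)
  u <- sort(pwcauchy(theta, mu, rho))
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
}

#' Bootstrap goodness-of-fit test for the wrapped Cauchy distribution
#'
#' Tests the null hypothesis that an angular sample is wrapped Cauchy, with
#' parameters unknown, using Watson's U-squared and parametric-bootstrap
#' critical values: the distribution is fitted to the data, and each
#' bootstrap replicate draws a sample of the same size from the fitted
#' distribution, re-estimates the parameters, and recomputes the statistic,
#' so the null distribution accounts for parameter estimation.
#'
#' @param theta numeric vector of angles, length at least 5.
#' @param reps bootstrap replicates (at least 100).
#' @param seed integer seed.
#' @param levels confidence levels for critical values.
#' @param fit_method estimator passed to [fit_wcauchy()].
#' @return an object of class `"wc_gof"`: list with `statistic`,
#'   `critical_values` (named by level), `reject` (logical per level),
#'   `p_value` (bootstrap proportion exceeding the observed statistic),
#'   `fitted` (the [fit_wcauchy()] estimate) and `reps`.
#' @examples
#' \donttest{
#' set.seed(2)
#' wcauchy_gof_test(rwcauchy(60, mu = 1, rho = 0.3), reps = 200, seed = 9)
#' }
#' @export
wcauchy_gof_test <- function(theta, reps = 500L, seed = 1L,
                             levels = c(0.90, 0.95, 0.99),
                             fit_method = "moment") {
  theta <- as_angles(theta)
  n <- length(theta)
  if (n < 5L) stop("need at least 5 angles", call. = FALSE)
  if (reps < 100L) stop("'reps' must be at least 100", call. = FALSE)
  fitted <- fit_wcauchy(theta, method = fit_method)
  obs <- watson_u2(theta, fitted$mu, fitted$rho)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  stats_b <- vapply(rep_seeds, function(s) {
    set.seed(s)
    th_b <- rwcauchy(n, fitted$mu, fitted$rho)
    fb <- fit_wcauchy(th_b, method = fit_method)
    watson_u2(th_b, fb$mu, fb$rho)
  }, numeric(1))
  crit <- stats::quantile(stats_b, probs = levels, type = 7, names = FALSE)
  structure(list(statistic = obs,
                 critical_values = stats::setNames(crit, levels),
                 reject = stats::setNames(obs > crit, levels),
                 p_value = mean(stats_b >= obs),
                 fitted = fitted, reps = reps),
            class = "wc_gof")
}

#' @export
print.wc_gof <- function(x, ...) {
  cat("Watson U-squared test of the wrapped Cauchy hypothesis\n")
  cat(sprintf("  fitted mu = %.4f, rho = %.4f (%s), n = %d\n",
              x$fitted$mu, x$fitted$rho, x$fitted$method, x$fitted$n))
  cat(sprintf("  U^2 = %.5f, bootstrap p-value = %.4f (%d reps)\n",
              x$statistic, x$p_value, x$reps))
  for (lv in names(x$critical_values)) {
    cat(sprintf("  level %s: critical value %.5f -> %s\n", lv,
                x$critical_values[[lv]],
                if (x$reject[[lv]]) "reject" else "retain"))
  }
  invisible(x)
}
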