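#' The wrapped Cauchy distribution
#'
#' Density, distribution function, random generation and parameter
#' estimation for the wrapped Cauchy distribution with mean direction `mu`
#' and concentration `rho` in `[0, 1)`. `rho = 0` is the circular uniform
#' distribution; `rho -> 1` concentrates all mass at `mu`. Relative to the
#' von Mises family the wrapped Cauchy is heavy-tailed, which is the error
#' model the outlier-detection machinery in this package assumes.
#'
#' The density is
#' \deqn{f(\theta) = \frac{1 - \rho^2}{2\pi\,(1 + \rho^2 -
#'   2\rho\cos(\theta - \mu))}.}
#'
#' `pwcauchy` returns arc-length probability accumulated counter-clockwise
#' from the reference angle `from` (default `mu - pi`, the antimode); the
#' anchor is a convention only and cancels in rotation-invariant statistics
#' such as Watson's U-squared.
#'
#' Sampling wraps a Cauchy variate with location `mu` and scale `-log(rho)`
#' onto the circle, which has exactly the wrapped Cauchy marginal
#' (`rho = exp(-gamma)` for a Cauchy scale `gamma`).
#'
#' @param theta numeric vector of angles in radians.
#' @param mu mean direction in radians.
#' @param rho concentration, a single number in `[0, 1)`.
#' @param n number of draws, a positive integer.
#' @param from reference angle at which the distribution function is zero.
#' @return `dwcauchy` the density, `pwcauchy` probabilities in `[0, 1]`,
#'   `rwcauchy` a vector of `n` angles in `[0, 2*pi)`.
#' @examples
#' dwcauchy(0, mu = 0, rho = 0)        # 1 / (2*pi)
#' pwcauchy(pi, mu = 0, rho = 0.5, from = 0)
#' set.seed(1); resultant_length(rwcauchy(1e4, mu = 0, rho = 0.7))
#' @name wcauchy
NULL

check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 0 || rho >= 1) {
    stop("'rho' must be a single number in [0, 1)", call. = FALSE)
  }
  rho
}

#' @rdname wcauchy
#' @export
dwcauchy <- function(theta, mu, rho) {
  check_rho(rho)
  theta <- as_angles(theta)
  mu <- as_angles(mu)
  (1 - rho^2) / (2 * pi * (1 + rho^2 - 2 * rho * cos(theta - mu)))
}

#' @rdname wcauchy
#' @export
pwcauchy <- function(theta, mu, rho, from = mu - pi) {
  check_rho(rho)
  if (length(from) != 1L || !is.finite(from)) {
    stop("'from' must be a single finite angle", call. = FALSE)
  }
  p <- wc_cdf_anchored(theta, mu, rho) - wc_cdf_anchored(from, mu, rho)
  p <- p %% 1
  # theta exactly `from` (mod 2*pi) means zero arc, not a full turn
  p[circ_distance(theta, from) < 1e-14 & p > 0.5] <- 0
  p
}

# CDF anchored at the antimode mu - pi, via the closed-form antiderivative
# (1/pi) * atan(((1 + rho)/(1 - rho)) * tan((theta - mu)/2)) per branch.
wc_cdf_anchored <- function(theta, mu, rho) {
  psi <- ((theta - mu + pi) %% (2 * pi)) - pi  # in [-pi, pi)
  0.5 + atan2((1 + rho) * sin(psi / 2), (1 - rho) * cos(psi / 2)) / pi
}

#' @rdname wcauchy
#' @export
rwcauchy <- function(n, mu, rho) {
  check_rho(rho)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (rho == 0) {
    return(stats::runif(n, 0, 2 * pi))
  }
  as_angles(stats::rcauchy(n, location = mu, scale = -log(rho)))
}

#' Fit a wrapped Cauchy distribution
#'
#' Estimates the mean direction `mu` and concentration `rho` from an angular
#' sample. The default is the moment estimator (`mu` = mean direction,
#' `rho` = mean resultant length, exact for the wrapped Cauchy since
#' `E[cos(theta - mu)] = rho`). `method = "ml"` refines both parameters by
#' maximizing the wrapped Cauchy log-likelihood numerically, starting from
#' the moment estimate. `rho` is clipped to `[0, 1 - 1e-9]` so a degenerate
#' (constant) sample still yields a valid parameter set.
#'
#' @param theta numeric vector of angles in radians, length at least 2.
#' @param method `"moment"` (default) or `"ml"`.
#' @return an object of class `"wc_params"`: a list with elements `mu`,
#'   `rho`, `method` and `n`.
#' @examples
#' set.seed(1)
#' fit_wcauchy(rwcauchy(500, mu = 2, rho = 0.6))
#' @export
fit_wcauchy <- function(theta, method = c("moment", "ml")) {
  method <- match.arg(method)
  theta <- as_angles(theta)
  if (length(theta) < 2L) stop("need at least 2 angles", call. = FALSE)
  mu <- mean_direction(theta)  # errors on zero resultant
  rho <- min(resultant_length(theta), 1 - 1e-9)
  if (method == "ml") {
    nll <- function(p) {
      -sum(log(dwcauchy(theta, p[1], p[2])))
    }
    opt <- stats::optim(c(mu, max(rho, 1e-6)), nll, method = "L-BFGS-B",
                        lower = c(mu - pi, 1e-9), upper = c(mu + pi, 1 - 1e-9))
    mu <- as_angles(opt$par[1])
    rho <- opt$par[2]
  }
  structure(list(mu = mu, rho = rho, method = method, n = length(theta)),
            class = "wc_params")
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wrapped Cauchy parameters (", x$method, " estimate, n = ", x$n,
      ")\n", sep = "")
  cat(sprintf("  mean direction mu : %.4f rad\n", x$mu))
  cat(sprintf("  concentration rho : %.4f\n", x$rho))
  invisible(x)
}
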