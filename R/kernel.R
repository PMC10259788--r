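#' Regression data with a linear predictor and an angular response
#'
#' Container for paired observations `(x_i, y_i)` where `x` is a real-valued
#' predictor and `y` an angular response stored in radians in `[0, 2*pi)`.
#'
#' @param x numeric predictor vector, finite.
#' @param y numeric response vector of angles, same length as `x`.
#' @param units units of `y`: `"radians"` (default) or `"degrees"`.
#' @return an object of class `"circ_data"`: a list with elements `x` and
#'   `y` (radians).
#' @export
circ_data <- function(x, y, units = c("radians", "degrees")) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (length(x) && any(!is.finite(x))) {
    stop("'x' must be finite", call. = FALSE)
  }
  y <- as_angles(y, units = match.arg(units))
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length", call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = y), class = "circ_data")
}

#' @export
print.circ_data <- function(x, ...) {
  cat("Linear-circular regression data: n =", length(x$x), "\n")
  invisible(x)
}

check_fit_data <- function(data) {
  if (!inherits(data, "circ_data")) data <- circ_data(data$x, data$y)
  if (length(data$x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(data$x)) < 2L) {
    stop("need at least two distinct predictor values", call. = FALSE)
  }
  data
}

# Gaussian kernel weight matrix for rows of x differences, with row-wise
# bandwidth widening (double h until a row has numerically positive mass).
# `exclude` gives, per evaluation row, the column index to zero out
# (leave-one-out), or 0 for none.
kernel_weight_matrix <- function(x_eval, x, h, exclude = NULL,
                                 warn = TRUE) {
  D <- outer(x_eval, x, "-")
  m <- length(x_eval)
  h_row <- rep(h, m)
  W <- exp(-(D * D) / (2 * h_row^2))
  if (!is.null(exclude)) {
    keep <- which(exclude > 0L)
    W[cbind(keep, exclude[keep])] <- 0
  }
  bad <- rowSums(W) == 0
  widened <- FALSE
  while (any(bad)) {
    widened <- TRUE
    h_row[bad] <- h_row[bad] * 2
    Wb <- exp(-(D[bad, , drop = FALSE]^2) / (2 * h_row[bad]^2))
    W[bad, ] <- Wb
    if (!is.null(exclude)) {
      keep <- which(exclude > 0L)
      W[cbind(keep, exclude[keep])] <- 0
    }
    bad <- rowSums(W) == 0
  }
  if (widened && warn) {
    warning("kernel bandwidth widened locally at evaluation points with no ",
            "neighbour mass", call. = FALSE)
  }
  W
}

#' Nadaraya-Watson estimator for a circular response
#'
#' Kernel-weighted mean direction: at each evaluation point the fitted angle
#' is `atan2(sum(w * sin(y)), sum(w * cos(y)))` with Gaussian weights
#' `w_i = exp(-(x - x_i)^2 / (2 h^2))`, reduced to `[0, 2*pi)`. As
#' `h -> Inf` the weights equalize and the fit collapses to the sample mean
#' direction everywhere.
#'
#' Evaluation points whose weights all underflow are handled by locally
#' doubling the bandwidth until a neighbour has positive mass (with a
#' warning).
#'
#' @param data a [circ_data()] object (or list with `x`, `y`).
#' @param h bandwidth, a single positive number.
#' @param x_eval numeric vector of evaluation points (default: the data
#'   `x`).
#' @return numeric vector of fitted angles in `[0, 2*pi)`, one per
#'   evaluation point.
#' @seealso [ll_fit()], [cv_bandwidth()], [circ_fit()]
#' @export
nw_fit <- function(data, h, x_eval = data$x) {
  data <- check_fit_data(data)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive bandwidth", call. = FALSE)
  }
  W <- kernel_weight_matrix(x_eval, data$x, h)
  nw_from_weights(W, data$y)
}

nw_from_weights <- function(W, y) {
  as_angles(atan2(W %*% sin(y), W %*% cos(y))[, 1])
}

#' Local-linear estimator for a circular response
#'
#' Fits weighted local-linear smooths separately to `sin(y)` and `cos(y)`
#' (the intercept of the local line at each evaluation point, Gaussian
#' kernel weights) and combines them with the four-quadrant arctangent. For
#' a response whose sine and cosine components are exactly linear in `x`,
#' the estimator is exact at any bandwidth. Where the weighted local design
#' is singular (all effective weight on one `x` value) the fit falls back to
#' the Nadaraya-Watson value at that point with a warning.
#'
#' @inheritParams nw_fit
#' @return numeric vector of fitted angles in `[0, 2*pi)`.
#' @seealso [nw_fit()], [cv_bandwidth()], [circ_fit()]
#' @export
ll_fit <- function(data, h, x_eval = data$x) {
  data <- check_fit_data(data)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive bandwidth", call. = FALSE)
  }
  W <- kernel_weight_matrix(x_eval, data$x, h)
  D <- outer(x_eval, data$x, "-")
  ll_from_weights(W, D, data$y, warn_singular = TRUE)
}

# Closed-form weighted least squares intercepts for sin and cos components.
# W: weights (m x n), D: x_j - x_eval_i differences (m x n).
ll_from_weights <- function(W, D, y, warn_singular = FALSE) {
  sy <- sin(y); cy <- cos(y)
  WD <- W * D
  S0 <- rowSums(W)
  S1 <- -rowSums(WD)          # sum w * (x_j - x_eval)
  S2 <- rowSums(WD * D)
  T0s <- (W %*% sy)[, 1]; T1s <- -(WD %*% sy)[, 1]
  T0c <- (W %*% cy)[, 1]; T1c <- -(WD %*% cy)[, 1]
  den <- S0 * S2 - S1^2
  scale <- S0 * S2 + S1^2
  singular <- den <= 1e-12 * pmax(scale, .Machine$double.xmin)
  bs <- (S2 * T0s - S1 * T1s) / den
  bc <- (S2 * T0c - S1 * T1c) / den
  if (any(singular)) {
    if (warn_singular) {
      warning("singular local design at ", sum(singular),
              " evaluation point(s); falling back to Nadaraya-Watson there",
              call. = FALSE)
    }
    bs[singular] <- T0s[singular]
    bc[singular] <- T0c[singular]
  }
  as_angles(atan2(bs, bc))
}

#' Default bandwidth grid
#'
#' Geometric grid of `length` points spanning `[0.05 * sd(x),
#' 2 * range(x)]`, wide enough to bracket both near-interpolation and
#' global-mean-direction regimes.
#'
#' @param x numeric predictor vector.
#' @param length number of grid points.
#' @return increasing numeric vector of bandwidths.
#' @export
default_bandwidth_grid <- function(x, length = 30L) {
  lo <- 0.05 * stats::sd(x)
  hi <- 2 * diff(range(x))
  if (!is.finite(lo) || lo <= 0) lo <- 1e-3
  if (!is.finite(hi) || hi <= lo) hi <- lo * 100
  exp(seq(log(lo), log(hi), length.out = length))
}

#' Leave-one-out cross-validated bandwidth
#'
#' For each candidate bandwidth, computes the leave-one-out score
#' `sum_i -cos(y_i - fhat_{-i}(x_i))`, where `fhat_{-i}` is the chosen
#' estimator fitted with the pair `(x_i, y_i)` excluded, and returns the
#' grid minimizer. The score lies in `[-n, n]`; ties are broken by the
#' smallest bandwidth.
#'
#' @param data a [circ_data()] object.
#' @param method `"NW"` or `"LL"`.
#' @param grid numeric vector of positive candidate bandwidths (default
#'   [default_bandwidth_grid()]).
#' @return a list with `h_opt`, `cv_scores` (one per grid point) and
#'   `grid`.
#' @export
cv_bandwidth <- function(data, method = c("NW", "LL"),
                         grid = default_bandwidth_grid(data$x)) {
  method <- match.arg(method)
  data <- check_fit_data(data)
  if (length(grid) == 0L || any(!is.finite(grid)) || any(grid <= 0)) {
    stop("bandwidth grid must be nonempty and positive", call. = FALSE)
  }
  grid <- sort(grid)
  scores <- vapply(grid, function(h) {
    yhat <- loo_fitted(data$x, data$y, h, method)
    sum(-cos(data$y - yhat))
  }, numeric(1))
  list(h_opt = grid[which.min(scores)], cv_scores = scores, grid = grid)
}

# Leave-one-out fitted values at the data points themselves. Bandwidth
# widening and singular-design fallbacks are routine when the CV search
# visits extreme grid bandwidths, so no warnings are raised here.
loo_fitted <- function(x, y, h, method) {
  n <- length(x)
  W <- kernel_weight_matrix(x, x, h, exclude = seq_len(n), warn = FALSE)
  if (method == "NW") {
    nw_from_weights(W, y)
  } else {
    D <- outer(x, x, "-")
    ll_from_weights(W, D, y)
  }
}

#' Absolute circular residuals
#'
#' Elementwise circular distance between observed and fitted angles,
#' `e_i = pi - |pi - |y_i - yhat_i||`, each in `[0, pi]`.
#'
#' @param y,yhat angle vectors of equal length.
#' @return numeric vector of residual magnitudes in `[0, pi]`.
#' @export
circular_residuals <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  }
  circ_distance(y, yhat)
}

#' Mean circular error
#'
#' `mean(1 - cos(y - yhat))`: 0 for a perfect fit, 2 when every residual is
#' antipodal. A scalar summary of fit quality for angular responses.
#'
#' @inheritParams circular_residuals
#' @return a number in `[0, 2]`.
#' @export
mce <- function(y, yhat) {
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) {
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  }
  mean(1 - cos(y - yhat))
}

#' Fit a circular-response kernel regression
#'
#' High-level fitting wrapper: selects the bandwidth by leave-one-out
#' cross-validation (unless `h` is given) and fits the chosen estimator at
#' the data points. Two sets of absolute circular residuals are returned:
#' `residuals` from the in-sample fitted values, and `deleted_residuals`
#' from the leave-one-out fitted values at the same bandwidth. Deleted
#' residuals carry no self-influence — an observation does not pull its own
#' fitted value toward itself — which is what the outlier-detection
#' statistic uses by default (see [detect_outliers()]).
#'
#' @inheritParams cv_bandwidth
#' @param h optional fixed bandwidth; `NULL` (default) selects by CV.
#' @return an object of class `"circ_fit"`: list with `method`, `h`,
#'   `cv_score` (`NA` when `h` was fixed), `fitted`, `residuals`,
#'   `loo_fitted`, `deleted_residuals` (all residuals are absolute circular
#'   residuals in `[0, pi]`), `mce` and the `data`.
#' @examples
#' d <- generate_model_data(60, rho = 0.9, seed = 7)
#' f <- circ_fit(d, method = "LL")
#' f$h; range(f$deleted_residuals)
#' @export
circ_fit <- function(data, method = c("NW", "LL"), h = NULL,
                     grid = default_bandwidth_grid(data$x)) {
  method <- match.arg(method)
  data <- check_fit_data(data)
  cv_score <- NA_real_
  if (is.null(h)) {
    cv <- cv_bandwidth(data, method, grid)
    h <- cv$h_opt
    cv_score <- min(cv$cv_scores)
  }
  yhat <- if (method == "NW") nw_fit(data, h) else ll_fit(data, h)
  yhat_loo <- loo_fitted(data$x, data$y, h, method)
  structure(list(method = method, h = h, cv_score = cv_score,
                 fitted = yhat,
                 residuals = circular_residuals(data$y, yhat),
                 loo_fitted = yhat_loo,
                 deleted_residuals = circular_residuals(data$y, yhat_loo),
                 mce = mce(data$y, yhat), data = data),
            class = "circ_fit")
}

# Residual vector of the type the detection pipeline asks for.
fit_residuals <- function(fit, residual_type = c("deleted", "fitted")) {
  switch(match.arg(residual_type),
         deleted = fit$deleted_residuals,
         fitted = fit$residuals)
}

#' @export
print.circ_fit <- function(x, ...) {
  cat("Circular-response kernel regression (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, bandwidth h = %.4g", length(x$fitted), x$h))
  if (!is.na(x$cv_score)) cat(sprintf(" (CV score %.4f)", x$cv_score))
  cat(sprintf("\n  mean circular error = %.4f\n", x$mce))
  invisible(x)
}
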