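#' Reduce angles to the canonical range [0, 2*pi)
#'
#' All angular quantities in circout live in radians in `[0, 2*pi)`. This
#' helper validates and reduces arbitrary finite numeric input, optionally
#' converting from degrees first. Reduction is idempotent.
#'
#' @param theta numeric vector of angles.
#' @param units `"radians"` (default) or `"degrees"`.
#' @return numeric vector of the same length, each element in `[0, 2*pi)`.
#' @examples
#' as_angles(c(-pi, 3 * pi))
#' as_angles(c(0, 90, 180, 359.9), units = "degrees")
#' @export
as_angles <- function(theta, units = c("radians", "degrees")) {
  units <- match.arg(units)
  if (!is.numeric(theta)) {
    stop("angles must be numeric", call. = FALSE)
  }
  if (length(theta) && any(!is.finite(theta))) {
    stop("angles must be finite", call. = FALSE)
  }
  if (units == "degrees") theta <- theta * (pi / 180)
  theta <- theta %% (2 * pi)
  # guard against x %% 2*pi returning exactly 2*pi for tiny negative x
  theta[theta >= 2 * pi] <- 0
  theta
}

#' Convert between degrees and radians
#'
#' @param x numeric vector.
#' @return numeric vector, converted.
#' @export
deg2rad <- function(x) x * (pi / 180)

#' @rdname deg2rad
#' @export
rad2deg <- function(x) x * (180 / pi)

#' Circular distance between two angles
#'
#' Shortest arc length between angles `a` and `b`,
#' `pi - |pi - |a - b||` after reducing `|a - b|` modulo `2*pi`.
#' The distance is symmetric and can never exceed `pi`; antipodal points
#' attain the maximum.
#'
#' @param a,b numeric vectors of angles in radians (any real values;
#'   reduced internally). Recycled to a common length.
#' @return numeric vector of distances in `[0, pi]`.
#' @examples
#' circ_distance(0, pi)            # pi, the maximum
#' circ_distance(0.5, 2 * pi - 0.5) # 1, the short way around
#' @export
circ_distance <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("angles must be numeric", call. = FALSE)
  }
  if ((length(a) && any(!is.finite(a))) || (length(b) && any(!is.finite(b)))) {
    stop("angles must be finite", call. = FALSE)
  }
  d <- abs(a - b) %% (2 * pi)
  pi - abs(pi - d)
}

#' Mean direction of a circular sample
#'
#' Direction of the resultant vector: the four-quadrant arctangent of
#' `(S, C)` with `S = sum(sin(theta))`, `C = sum(cos(theta))`, reduced to
#' `[0, 2*pi)`. Undefined when the resultant length vanishes (e.g. for
#' perfectly balanced antipodal samples).
#'
#' @param theta numeric vector of angles in radians, nonempty.
#' @return a single angle in `[0, 2*pi)`.
#' @seealso [resultant_length()], [circular_median()]
#' @export
mean_direction <- function(theta) {
  theta <- as_angles(theta)
  if (length(theta) == 0L) stop("empty angle vector", call. = FALSE)
  S <- sum(sin(theta))
  C <- sum(cos(theta))
  if (sqrt(S^2 + C^2) / length(theta) < 1e-12) {
    stop("mean direction undefined: resultant length is zero", call. = FALSE)
  }
  as_angles(atan2(S, C))
}

#' Mean resultant length of a circular sample
#'
#' `sqrt(S^2 + C^2) / n`: 1 for a constant sample, 0 under perfect
#' cancellation. For a wrapped Cauchy sample this is the moment estimator of
#' the concentration rho, since `E[cos(theta - mu)] = rho`.
#'
#' @inheritParams mean_direction
#' @return a number in `[0, 1]`.
#' @export
resultant_length <- function(theta) {
  theta <- as_angles(theta)
  if (length(theta) == 0L) stop("empty angle vector", call. = FALSE)
  S <- sum(sin(theta))
  C <- sum(cos(theta))
  min(1, sqrt(S^2 + C^2) / length(theta))
}

#' Circular median of a sample
#'
#' The angle minimizing the mean circular distance to the sample,
#' `d(theta) = mean(circ_distance(theta_i, theta))`. The minimization is
#' carried out over the observed angles themselves (the standard sample
#' circular median); ties are broken by the smallest candidate angle in
#' `[0, 2*pi)`. More robust than the mean direction under asymmetric
#' contamination.
#'
#' @inheritParams mean_direction
#' @return a single angle from the sample, in `[0, 2*pi)`.
#' @export
circular_median <- function(theta) {
  theta <- as_angles(theta)
  n <- length(theta)
  if (n == 0L) stop("empty angle vector", call. = FALSE)
  if (n == 1L) return(theta)
  D <- abs(outer(theta, theta, "-")) %% (2 * pi)
  D <- pi - abs(pi - D)
  obj <- colMeans(D)
  best <- min(obj)
  min(theta[obj <= best + 1e-12])
}

#' @keywords internal
#' Mean circular distance from a candidate angle to a sample; the objective
#' the circular median minimizes. Used by tests and diagnostics.
#' @noRd
circ_median_objective <- function(theta, candidate) {
  mean(circ_distance(theta, candidate))
}
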