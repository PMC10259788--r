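#' Mean curve of the reference simulation model
#'
#' `m(x) = sin(1.5 x - pi/2) + (4/3) cos(x/3)`, the regression function used
#' throughout the cut-off calibration and the simulation study.
#'
#' @param x numeric vector.
#' @return numeric vector of angles (not yet reduced).
#' @export
model_mean_curve <- function(x) {
  sin(1.5 * x - pi / 2) + (4 / 3) * cos(x / 3)
}

#' Generate data from the reference linear-circular model
#'
#' Draws `x ~ Normal(mean 3, variance 0.25)` and sets
#' `y = (m(x) + eps) mod 2*pi` with wrapped Cauchy errors
#' `eps ~ WC(0, rho)`. This is the null (uncontaminated) data-generating
#' model under which the detection cut-offs are calibrated.
#'
#' @param n sample size, at least 3.
#' @param rho error concentration in `[0, 1)`.
#' @param seed optional integer seed for reproducibility.
#' @param mean_function the regression function; defaults to
#'   [model_mean_curve()]. Exposed as a hook so alternative mean curves can
#'   be calibrated with the same machinery.
#' @param x_mean,x_sd predictor distribution parameters (defaults: mean 3,
#'   standard deviation 0.5, i.e. variance 0.25).
#' @return a [circ_data()] object with attribute `"mean_values"` holding
#'   `m(x) mod 2*pi` (the noiseless truth).
#' @export
generate_model_data <- function(n, rho, seed = NULL,
                                mean_function = model_mean_curve,
                                x_mean = 3, x_sd = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3) {
    stop("'n' must be a single integer >= 3", call. = FALSE)
  }
  check_rho(rho)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, x_mean, x_sd)
  eps <- rwcauchy(n, mu = 0, rho = rho)
  d <- circ_data(x, mean_function(x) + eps)
  attr(d, "mean_values") <- as_angles(mean_function(x))
  d
}
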