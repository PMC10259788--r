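#' Distances of absolute circular residuals from their circular median
#'
#' The detection statistic: given absolute circular residuals `e`, computes
#' `dist_i = pi - |pi - |e_i - cmed||` where `cmed` is the circular median
#' of the residuals.
#'
#' @param e numeric vector of absolute circular residuals in `[0, pi]`.
#' @return a list with `distances` (in `[0, pi]`) and `median` (cmed).
#' @export
median_distances <- function(e) {
  cmed <- circular_median(e)
  list(distances = circ_distance(e, cmed), median = cmed)
}

#' Detection-statistic quantiles for one null replicate
#'
#' Runs the full null pipeline once: generates a clean dataset from the
#' reference model, selects the bandwidth by leave-one-out CV, fits the
#' chosen estimator, computes absolute circular residuals (deleted, by
#' default), their distances from the circular median, and returns the
#' empirical quantiles of those distances (type-7, the R default).
#'
#' @param n sample size.
#' @param rho wrapped Cauchy error concentration.
#' @param method `"NW"` or `"LL"`.
#' @param q numeric vector of quantile levels in (0, 1).
#' @param seed optional integer seed.
#' @param mean_function regression function hook, see
#'   [generate_model_data()].
#' @param grid_length number of points in the CV bandwidth grid.
#' @param residual_type `"deleted"` (leave-one-out residuals, the default)
#'   or `"fitted"` (in-sample residuals); see [circ_fit()].
#' @return numeric vector of quantiles, one per element of `q`.
#' @export
single_rep_quantiles <- function(n, rho, method = c("NW", "LL"),
                                 q = c(0.90, 0.95, 0.99), seed = NULL,
                                 mean_function = model_mean_curve,
                                 grid_length = 30L,
                                 residual_type = c("deleted", "fitted")) {
  method <- match.arg(method)
  residual_type <- match.arg(residual_type)
  d <- generate_model_data(n, rho, seed = seed,
                           mean_function = mean_function)
  f <- circ_fit(d, method = method,
                grid = default_bandwidth_grid(d$x, grid_length))
  md <- median_distances(fit_residuals(f, residual_type))
  stats::quantile(md$distances, probs = q, type = 7, names = FALSE)
}

#' Monte-Carlo cut-off points for outlier detection
#'
#' Calibrates detection cut-offs under the null model: repeats
#' [single_rep_quantiles()] `reps` times and reports the mean quantile at
#' each level as the cut-off, together with its Monte-Carlo standard error.
#' A master seed spawns one substream seed per replicate, so results are
#' reproducible and replicate-order independent.
#'
#' @inheritParams single_rep_quantiles
#' @param reps number of Monte-Carlo replicates (2000 for full fidelity;
#'   smaller values trade precision for speed).
#' @param seed master integer seed.
#' @param residual_type residual definition, see [single_rep_quantiles()].
#' @return an object of class `"cutoff_mc"`: a data frame with columns
#'   `method`, `q`, `n`, `rho`, `cutoff`, `se`, `reps`.
#' @examples
#' \donttest{
#' generate_cutoffs(20, 0.10, "NW", reps = 100, seed = 1)
#' }
#' @export
generate_cutoffs <- function(n, rho, method = c("NW", "LL"),
                             q = c(0.90, 0.95, 0.99), reps = 2000L,
                             seed = 1L, mean_function = model_mean_curve,
                             grid_length = 30L,
                             residual_type = c("deleted", "fitted")) {
  method <- match.arg(method)
  residual_type <- match.arg(residual_type)
  if (!is.numeric(reps) || reps < 1) {
    stop("'reps' must be a positive integer", call. = FALSE)
  }
  reps <- as.integer(reps)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  Q <- vapply(rep_seeds, function(s) {
    single_rep_quantiles(n, rho, method, q, seed = s,
                         mean_function = mean_function,
                         grid_length = grid_length,
                         residual_type = residual_type)
  }, numeric(length(q)))
  Q <- matrix(Q, nrow = length(q))  # levels x reps
  cut <- rowMeans(Q)
  se <- if (reps > 1) apply(Q, 1, stats::sd) / sqrt(reps) else rep(NA_real_, length(q))
  structure(data.frame(method = method, q = q, n = n, rho = rho,
                       cutoff = cut, se = se, reps = reps),
            class = c("cutoff_mc", "data.frame"))
}

#' Load the packaged cut-off tables
#'
#' Cut-off points calibrated for the reference model (Gaussian-kernel NW
#' and LL estimators, CV bandwidths, wrapped Cauchy errors), on the grid
#' n in \{20, 30, 40, 50, 100, 200\}, rho in \{0.10, ..., 0.99\} and
#' q in \{0.90, 0.95, 0.99\}, shipped as a plain CSV. These can be
#' regenerated (at Monte-Carlo precision) with [generate_cutoffs()].
#'
#' @param path CSV path; defaults to the copy installed with the package.
#' @return an object of class `"cutoff_table"`: a data frame with columns
#'   `method`, `q`, `n`, `rho`, `cutoff`.
#' @export
load_cutoff_table <- function(path = system.file("extdata",
                                                 "cutoff_tables.csv",
                                                 package = "circout")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("method", "q", "n", "rho", "cutoff")
  if (!all(need %in% names(tab))) {
    stop("cut-off table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  structure(tab, class = c("cutoff_table", "data.frame"))
}

#' Look up a cut-off point, interpolating between tabulated cells
#'
#' Returns the tabulated cut-off when `(n, rho)` falls on the table grid;
#' otherwise interpolates bilinearly in `(n, rho)`. Queries outside the rho
#' grid are clamped to the nearest tabulated rho with a warning; `n` above
#' the largest tabulated size is likewise clamped. `n` below the smallest
#' tabulated size is an error unless `extrapolate = TRUE` (which clamps).
#' The quantile level must be tabulated exactly.
#'
#' @param table a `"cutoff_table"` data frame, see [load_cutoff_table()].
#' @param n sample size of the query.
#' @param rho concentration of the query.
#' @param q quantile level (must be present in the table).
#' @param method `"NW"` or `"LL"`.
#' @param extrapolate allow clamping below the smallest tabulated `n`.
#' @return a single cut-off value in radians.
#' @export
lookup_cutoff <- function(table, n, rho, q, method = c("NW", "LL"),
                          extrapolate = FALSE) {
  method <- match.arg(method)
  sub <- table[table$method == method & abs(table$q - q) < 1e-9, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("quantile level q = ", q, " is not tabulated for method ", method,
         call. = FALSE)
  }
  ns <- sort(unique(sub$n))
  rhos <- sort(unique(sub$rho))
  if (n < min(ns)) {
    if (!extrapolate) {
      stop("n = ", n, " is below the smallest tabulated sample size (",
           min(ns), "); set extrapolate = TRUE to clamp", call. = FALSE)
    }
    warning("n clamped up to the smallest tabulated sample size",
            call. = FALSE)
    n <- min(ns)
  }
  if (n > max(ns)) {
    warning("n clamped down to the largest tabulated sample size",
            call. = FALSE)
    n <- max(ns)
  }
  if (rho < min(rhos) || rho > max(rhos)) {
    warning("rho outside the tabulated grid; clamped to the nearest ",
            "tabulated value", call. = FALSE)
    rho <- min(max(rho, min(rhos)), max(rhos))
  }
  cell <- function(n0, r0) {
    v <- sub$cutoff[sub$n == n0 & abs(sub$rho - r0) < 1e-9]
    if (length(v) != 1L) {
      stop("cut-off table cell (n = ", n0, ", rho = ", r0,
           ") missing or duplicated", call. = FALSE)
    }
    v
  }
  bracket <- function(grid, v) {
    if (any(abs(grid - v) < 1e-9)) {
      g <- grid[which.min(abs(grid - v))]
      return(list(lo = g, hi = g, w = 0))
    }
    lo <- max(grid[grid < v]); hi <- min(grid[grid > v])
    list(lo = lo, hi = hi, w = (v - lo) / (hi - lo))
  }
  bn <- bracket(ns, n)
  br <- bracket(rhos, rho)
  v00 <- cell(bn$lo, br$lo); v01 <- cell(bn$lo, br$hi)
  v10 <- cell(bn$hi, br$lo); v11 <- cell(bn$hi, br$hi)
  (1 - bn$w) * ((1 - br$w) * v00 + br$w * v01) +
    bn$w * ((1 - br$w) * v10 + br$w * v11)
}
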