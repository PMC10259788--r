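#' Contaminate an angular response with antipodal-type shifts
#'
#' Shifts selected observations by `gamma * pi` (mod `2*pi`), the standard
#' response-outlier mechanism for circular regression: `gamma = 1` moves a
#' point to its antipode, `gamma = 0` leaves it unchanged. When explicit
#' indices are not supplied, `max(1, round(fraction * n))` indices are drawn
#' uniformly at random without replacement (a nominal fraction below `1/n`
#' still contaminates one point).
#'
#' @param y numeric vector of angles in radians.
#' @param gamma contamination degree in `[0, 1]`.
#' @param fraction proportion of observations to contaminate (ignored when
#'   `indices` is given).
#' @param indices optional explicit indices to contaminate.
#' @param seed optional integer seed for the index draw.
#' @return a list with `y` (contaminated angles) and `indices` (sorted
#'   contaminated indices).
#' @export
contaminate <- function(y, gamma, fraction = NULL, indices = NULL,
                        seed = NULL) {
  y <- as_angles(y)
  n <- length(y)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("'gamma' must be a single number in [0, 1]", call. = FALSE)
  }
  if (is.null(indices)) {
    if (is.null(fraction)) {
      stop("supply either 'fraction' or 'indices'", call. = FALSE)
    }
    k <- max(1L, as.integer(round(fraction * n)))
    if (k > n) stop("contamination fraction exceeds the sample", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    indices <- sample.int(n, k)
  } else {
    indices <- as.integer(indices)
    if (any(indices < 1L) || any(indices > n) || anyDuplicated(indices)) {
      stop("'indices' must be distinct indices into 'y'", call. = FALSE)
    }
  }
  y[indices] <- as_angles(y[indices] + gamma * pi)
  list(y = y, indices = sort(indices))
}

#' Detection performance against a known truth
#'
#' Scores a flagged index set against the true outlier set:
#' masking `M = |truth setdiff flagged| / |truth|` (true outliers missed),
#' swamping `S = |flagged setdiff truth| / (n - |truth|)` (inliers wrongly
#' flagged), and the true detection rate
#' `TDR = |flagged intersect truth| / |truth| = 1 - M`.
#'
#' @param flagged integer vector of flagged indices.
#' @param truth integer vector of true outlier indices (nonempty).
#' @param n total sample size, strictly greater than `|truth|`.
#' @return a list with `tdr`, `masking`, `swamping`.
#' @export
detection_performance <- function(flagged, truth, n) {
  truth <- unique(as.integer(truth))
  flagged <- unique(as.integer(flagged))
  if (length(truth) == 0L) {
    stop("masking and TDR are undefined for an empty truth set",
         call. = FALSE)
  }
  if (n <= length(truth)) {
    stop("swamping is undefined when every observation is an outlier",
         call. = FALSE)
  }
  hit <- sum(flagged %in% truth)
  list(tdr = hit / length(truth),
       masking = (length(truth) - hit) / length(truth),
       swamping = sum(!(flagged %in% truth)) / (n - length(truth)))
}

#' Run a simulation-study design for the detection method
#'
#' Full crossover over sample size, error concentration, contamination
#' degree, contaminated fraction and estimator: each replicate generates
#' clean data from the reference model, contaminates it, fits with a CV
#' bandwidth, applies the cut-off, and scores TDR, masking, swamping and
#' the mean circular error of the fit. By default the cut-off is looked up
#' at the replicate's true simulation rho (the calibration tables are
#' indexed by the error concentration); `rho_lookup = "estimated"` instead
#' uses the rho estimated from the residuals, quantifying the practical gap
#' when rho is unknown.
#'
#' @param n,rho,gamma,fraction numeric vectors of factor levels.
#' @param method character vector from `c("NW", "LL")`.
#' @param q quantile level(s) of the cut-off.
#' @param reps replicates per design cell.
#' @param seed master integer seed.
#' @param cutoff_table table for cut-off lookup (default: packaged tables).
#' @param rho_lookup `"true"` (default) or `"estimated"`.
#' @return a data frame with one row per design cell: factor levels plus
#'   `tdr`, `masking`, `swamping`, `mce`, `se_tdr` and `reps`.
#' @examples
#' \donttest{
#' run_design(n = 40, rho = 0.9, gamma = 0.85, fraction = 0.05,
#'            method = "NW", reps = 20, seed = 1)
#' }
#' @export
run_design <- function(n, rho, gamma, fraction, method = "NW", q = 0.95,
                       reps = 500L, seed = 1L,
                       cutoff_table = load_cutoff_table(),
                       rho_lookup = c("true", "estimated")) {
  rho_lookup <- match.arg(rho_lookup)
  method <- match.arg(method, c("NW", "LL"), several.ok = TRUE)
  cells <- expand.grid(method = method, q = q, n = n, rho = rho,
                       gamma = gamma, fraction = fraction,
                       stringsAsFactors = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    cutoff <- if (rho_lookup == "true") {
      lookup_cutoff(cutoff_table, n = cl$n, rho = cl$rho, q = cl$q,
                    method = cl$method, extrapolate = TRUE)
    } else {
      NA_real_
    }
    set.seed(cell_seeds[i])
    rep_seeds <- sample.int(.Machine$integer.max, reps)
    perf <- vapply(rep_seeds, function(s) {
      d <- generate_model_data(cl$n, cl$rho, seed = s)
      cont <- contaminate(d$y, cl$gamma, fraction = cl$fraction)
      dc <- circ_data(d$x, cont$y)
      res <- if (rho_lookup == "true") {
        detect_outliers(dc, method = cl$method, q = cl$q,
                        cutoff_source = cutoff)
      } else {
        detect_outliers(dc, method = cl$method, q = cl$q,
                        cutoff_source = "table",
                        cutoff_table = cutoff_table)
      }
      p <- detection_performance(res$outliers, cont$indices, cl$n)
      c(p$tdr, p$masking, p$swamping, res$fit$mce)
    }, numeric(4))
    data.frame(method = cl$method, q = cl$q, n = cl$n, rho = cl$rho,
               gamma = cl$gamma, fraction = cl$fraction, reps = reps,
               tdr = mean(perf[1, ]), masking = mean(perf[2, ]),
               swamping = mean(perf[3, ]), mce = mean(perf[4, ]),
               se_tdr = stats::sd(perf[1, ]) / sqrt(reps))
  })
  do.call(rbind, rows)
}
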