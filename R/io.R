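#' Read a linear-circular dataset from delimited text
#'
#' Reads a delimited file with one real-valued predictor column and one
#' angular response column, converts the response to radians in
#' `[0, 2*pi)` and drops rows with missing values (reporting the count).
#'
#' @param path file path.
#' @param x_col,y_col column names of the predictor and the angular
#'   response.
#' @param units units of the response column: `"radians"` or `"degrees"`.
#' @param sep field delimiter (default `","`; use `"\t"` for TSV).
#' @return a [circ_data()] object.
#' @export
read_angular_data <- function(path, x_col, y_col,
                              units = c("radians", "degrees"), sep = ",") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c(x_col, y_col)) {
    if (!cl %in% names(df)) {
      stop("column '", cl, "' not found in ", path, call. = FALSE)
    }
  }
  x <- as.numeric(df[[x_col]])
  y <- as.numeric(df[[y_col]])
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message("dropped ", dropped, " row(s) with missing or non-finite values")
  }
  if (!any(keep)) stop("no usable rows after filtering", call. = FALSE)
  circ_data(x[keep], y[keep], units = units)
}

#' Write a linear-circular dataset to delimited text
#'
#' @param data a [circ_data()] object.
#' @param path output file path.
#' @param x_col,y_col column names to write.
#' @param units units for the response column on disk.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_angular_data <- function(data, path, x_col = "x", y_col = "theta",
                               units = c("radians", "degrees"), sep = ",") {
  units <- match.arg(units)
  y <- if (units == "degrees") rad2deg(data$y) else data$y
  df <- stats::setNames(data.frame(data$x, y), c(x_col, y_col))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Generate a benchmark fixture dataset
#'
#' Two reproducible fixtures with known ground truth. `"model"` draws from
#' the reference simulation model ([generate_model_data()]), optionally
#' contaminated, and records the true outlier indices. `"scada_like"` is a
#' synthetic stand-in for a wind-turbine SCADA extract: `n` wind-speed
#' (m/s) / wind-direction (degrees) pairs with a smooth speed-direction
#' relation centred near mean direction 1.074 rad, diffuse wrapped Cauchy
#' noise (`rho` about 0.18), and a few injected antipodal shifts. It mimics
#' only the summary properties of such data (sample size, mean direction,
#' concentration, a handful of outliers), not any real turbine's record.
#'
#' @param kind `"model"` or `"scada_like"`.
#' @param n sample size (defaults: 100 for `"model"`, 55 for
#'   `"scada_like"`).
#' @param seed integer seed.
#' @param rho error concentration.
#' @param gamma,fraction contamination settings (`"model"`: `gamma = 0`
#'   means clean data; `"scada_like"` always injects
#'   `max(1, round(fraction * n))` shifts of `0.9 * pi`).
#' @return a [circ_data()] object with attributes `"outliers"` (true
#'   outlier indices, possibly empty) and, for `"scada_like"`, `"units"`
#'   recording that the source scale was degrees.
#' @export
make_fixture <- function(kind = c("model", "scada_like"), n = NULL,
                         seed = 1L, rho = NULL, gamma = 0.85,
                         fraction = 0.05) {
  kind <- match.arg(kind)
  if (kind == "model") {
    if (is.null(n)) n <- 100L
    if (is.null(rho)) rho <- 0.90
    d <- generate_model_data(n, rho, seed = seed)
    truth <- integer(0)
    if (gamma > 0) {
      set.seed(seed + 1L)
      cont <- contaminate(d$y, gamma, fraction = fraction)
      d <- circ_data(d$x, cont$y)
      truth <- cont$indices
    }
    attr(d, "outliers") <- truth
    return(d)
  }
  # scada_like
  if (is.null(n)) n <- 55L
  if (is.null(rho)) rho <- 0.18
  set.seed(seed)
  speed <- stats::runif(n, 3, 12)                 # wind speed, m/s
  dir_mean <- 1.074 + 0.35 * sin(speed / 2.5)     # radians, smooth in speed
  eps <- rwcauchy(n, mu = 0, rho = rho)
  y <- as_angles(dir_mean + eps)
  k <- max(1L, as.integer(round(fraction * n)))
  idx <- sample.int(n, k)
  y[idx] <- as_angles(y[idx] + 0.9 * pi)
  d <- circ_data(speed, y)
  attr(d, "outliers") <- sort(idx)
  attr(d, "units") <- "degrees"
  d
}

#' Write a JSON detection report
#'
#' Serializes a [detect_outliers()] result: per-observation distances, the
#' applied cut-off, flags, and fit metadata (method, bandwidth, CV score,
#' residual concentration).
#'
#' @param result a `"circ_outliers"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(result, path) {
  stopifnot(inherits(result, "circ_outliers"))
  rep <- list(
    method = result$fit$method,
    q = result$q,
    n = length(result$distances),
    bandwidth = result$fit$h,
    cv_score = result$fit$cv_score,
    rho_hat = result$rho_hat,
    residual_median = result$residual_median,
    cutoff = result$cutoff,
    cutoff_source = result$cutoff_source,
    distances = result$distances,
    flagged = as.logical(result$distances > result$cutoff),
    outliers = as.integer(result$outliers)
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
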