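#' Extract threshold exceedances from a series
#'
#' Sets the threshold `u` at the `p`-quantile of the series and returns the
#' positive excesses `x - u` of all observations strictly above it — the
#' peaks-over-threshold sample every tail likelihood in the package consumes.
#'
#' The empirical quantile convention is the order statistic at index
#' `ceiling(p * n)` of the sorted sample, so `u` is always an observed value
#' and roughly `(1 - p) * n` observations exceed it. Alternatively, with
#' `type = "theoretical"` and a declared stable `family`, `u` is the exact
#' `p`-quantile of the standard member scaled by `a` — useful when replicating
#' simulation designs where the baseline is known.
#'
#' @param data a numeric vector, or a data frame whose first numeric column
#'   (or the column named by `col`) holds the series.
#' @param p tail level in (0, 1); the threshold is the `p`-quantile.
#' @param type `"empirical"` (default, order-statistic threshold) or
#'   `"theoretical"` (known-baseline quantile).
#' @param family,a for `type = "theoretical"`: the stable family and its
#'   scale `a` (location `b` is assumed 0).
#' @param col optional column name when `data` is a data frame.
#' @return an object of class `exceedances`: a tibble with column `excess`,
#'   carrying attributes `u` (threshold), `p`, `m` (number of exceedances)
#'   and `n_source` (length of the input series).
#' @examples
#' extract_exceedances(c(1, 2, 3, 4, 5), p = 0.6)  # u = 3, excesses 1, 2
#' @export
extract_exceedances <- function(data, p, type = c("empirical", "theoretical"),
                                family = NULL, a = 1, col = NULL) {
  type <- match.arg(type)
  x <- series_values(data, col)
  stopifnot(is.numeric(p), length(p) == 1, p > 0, p < 1)
  n <- length(x)
  if (type == "empirical") {
    u <- sort(x)[ceiling(p * n)]
  } else {
    if (is.null(family)) stop("`family` is required for a theoretical threshold", call. = FALSE)
    stopifnot(a > 0)
    u <- a * stable_std_quantile(family, p)
  }
  excess <- x[x > u] - u
  if (length(excess) == 0) {
    stop(sprintf("no observations exceed u = %g (p = %g)", u, p), call. = FALSE)
  }
  new_exceedances(excess, u = u, p = p, n_source = n)
}

new_exceedances <- function(excess, u, p, n_source) {
  out <- tibble::tibble(excess = as.numeric(excess))
  structure(out,
            u = u, p = p, m = length(excess), n_source = n_source,
            class = c("exceedances", class(out)))
}

#' @export
print.exceedances <- function(x, ...) {
  cat(sprintf("<exceedances> m = %d of n = %d above u = %g (p = %g)\n",
              attr(x, "m"), attr(x, "n_source"), attr(x, "u"), attr(x, "p")))
  NextMethod()
}

# accepts an exceedances object or a bare positive numeric vector
tail_values <- function(tail) {
  if (inherits(tail, "exceedances")) return(tail$excess)
  if (is.data.frame(tail) && "excess" %in% names(tail)) return(tail$excess)
  x <- as.numeric(tail)
  if (length(x) == 0 || any(x <= 0)) {
    stop("exceedances must be a non-empty set of positive excesses", call. = FALSE)
  }
  x
}

# pull the series out of a vector / data frame
series_values <- function(data, col = NULL) {
  if (is.data.frame(data)) {
    if (!is.null(col)) {
      x <- data[[col]]
      if (is.null(x)) stop(sprintf("column '%s' not found", col), call. = FALSE)
    } else {
      num <- vapply(data, is.numeric, logical(1))
      if (!any(num)) stop("no numeric column found in `data`", call. = FALSE)
      x <- data[[which(num)[1]]]
    }
  } else {
    x <- data
  }
  x <- as.numeric(x)
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("series is empty after dropping NA values", call. = FALSE)
  x
}

#' Read a univariate series from a text file
#'
#' Accepts either a plain text file with one value per line or a
#' single-column CSV with an optional header. Blank lines and values that do
#' not parse as numbers are dropped, with a message reporting the count.
#'
#' @param path file path.
#' @return a tibble with one numeric column `value`.
#' @export
read_series <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("file contains no data", call. = FALSE)
  # a single-column CSV may carry a header and/or trailing commas
  lines <- sub(",\\s*$", "", lines)
  vals <- suppressWarnings(as.numeric(lines))
  if (is.na(vals[1]) && length(lines) > 1) {   # header line
    lines <- lines[-1]
    vals <- suppressWarnings(as.numeric(lines))
  }
  dropped <- sum(is.na(vals))
  if (dropped > 0) message(sprintf("read_series: dropped %d non-numeric/blank entries", dropped))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no numeric values found in file", call. = FALSE)
  tibble::tibble(value = vals)
}
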