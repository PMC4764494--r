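#' Build a measurement table from raw batch/sample/value records
#'
#' A measurement table is the central container of calibatch: a sparse
#' collection of raw instrument readings \eqn{y_{ijk}}, each tagged with the
#' batch \eqn{i} it was acquired in (one immunoblot, one ELISA plate, one
#' spectrometer session, ...) and the sample \eqn{j} it was taken from.
#' Replicate measurements of the same sample within the same batch simply
#' repeat the (batch, sample) pair; the replicate index \eqn{k} is implicit
#' in row order and never supplied by the user.
#'
#' Batch and sample identifiers are opaque strings kept in first-appearance
#' order.  A cell of the conceptual batch-by-sample table may hold zero, one,
#' or several measurements; most cells are empty in realistic designs.
#'
#' @param batch either a data frame with columns `batch`, `sample` and
#'   `value` (one measurement per row), or a vector of batch identifiers.
#' @param sample vector of sample identifiers (ignored when `batch` is a
#'   data frame).
#' @param value numeric vector of raw measurement values, in instrument
#'   units (ignored when `batch` is a data frame).
#' @return An object of class `"measurement_table"`: a list with character
#'   vectors `batch` and `sample`, numeric `value`, and the ordered identifier
#'   sets `batches` and `samples`.
#' @examples
#' mt <- measurement_table(
#'   batch  = c("B1", "B1", "B2"),
#'   sample = c("S1", "S1", "S2"),
#'   value  = c(10.2, 11.0, 5.4))
#' mt
#' measurement_counts(mt)
#' @seealso [standard_set()], [calibrate()], [read_measurements()]
#' @export
measurement_table <- function(batch, sample = NULL, value = NULL) {
  if (is.data.frame(batch)) {
    df <- batch
    need <- c("batch", "sample", "value")
    miss <- setdiff(need, names(df))
    if (length(miss) > 0L) {
      stop("data frame input must have columns 'batch', 'sample', 'value'; missing: ",
           paste(miss, collapse = ", "))
    }
    batch <- df$batch
    sample <- df$sample
    value <- df$value
  }
  if (length(batch) == 0L) {
    stop("a measurement table needs at least one measurement")
  }
  if (length(sample) != length(batch) || length(value) != length(batch)) {
    stop("'batch', 'sample' and 'value' must have equal length")
  }
  batch <- as.character(batch)
  sample <- as.character(sample)
  value <- as.numeric(value)
  bad <- which(!is.finite(value))
  if (length(bad) > 0L) {
    stop(sprintf("non-finite measurement value at row %d (batch '%s', sample '%s')",
                 bad[1L], batch[bad[1L]], sample[bad[1L]]))
  }
  if (anyNA(batch) || anyNA(sample)) {
    stop("batch and sample identifiers must not be missing")
  }
  structure(
    list(batch = batch, sample = sample, value = value,
         batches = unique(batch), samples = unique(sample)),
    class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("Measurement table: %d measurements, %d batches x %d samples\n",
              n_measurements(x), length(x$batches), length(x$samples)))
  nm <- measurement_counts(x)
  filled <- sum(nm > 0L)
  cat(sprintf("  occupied cells: %d of %d (replicates per occupied cell: %.2f)\n",
              filled, length(nm), n_measurements(x) / filled))
  invisible(x)
}

#' @export
as.data.frame.measurement_table <- function(x, ...) {
  data.frame(batch = x$batch, sample = x$sample, value = x$value,
             stringsAsFactors = FALSE)
}

#' Measurement counts of a table
#'
#' `measurement_counts()` returns the full matrix of per-cell replicate
#' counts \eqn{n_{ij}} (batches in rows, samples in columns, both in
#' first-appearance order).  `n_measurements()` returns the grand total
#' \eqn{n_{All,All}}.  Row sums of the matrix are the per-batch totals
#' \eqn{n_{i,All}} and column sums the per-sample totals \eqn{n_{All,j}}.
#'
#' @param x a [measurement_table()].
#' @return An integer matrix with dimnames (batches, samples), or a single
#'   integer for `n_measurements()`.
#' @export
measurement_counts <- function(x) {
  stopifnot(inherits(x, "measurement_table"))
  bi <- factor(x$batch, levels = x$batches)
  sj <- factor(x$sample, levels = x$samples)
  unclass(table(bi, sj, dnn = NULL))
}

#' @rdname measurement_counts
#' @export
n_measurements <- function(x) {
  stopifnot(inherits(x, "measurement_table"))
  length(x$value)
}

# keep rows of a measurement table (internal); errors if nothing is left
mt_keep <- function(x, keep) {
  if (!any(keep)) stop("no measurements left in table")
  measurement_table(x$batch[keep], x$sample[keep], x$value[keep])
}

#' Define the set of standard samples
#'
#' Standards are samples whose analyte amounts are known a priori; they anchor
#' the calibration scale.  If no true standard exists, assign the role to one
#' of the unknown samples and all other amounts are estimated relative to it.
#'
#' @param x a named numeric vector mapping sample identifiers to known
#'   analyte amounts, or a data frame whose first two columns are sample
#'   identifier and amount.
#' @return A named numeric vector of class `"standard_set"`.
#' @examples
#' standard_set(c(Std1 = 5, Std2 = 15))
#' @export
standard_set <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("standard data frame needs sample and amount columns")
    amounts <- as.numeric(x[[2L]])
    names(amounts) <- as.character(x[[1L]])
    x <- amounts
  }
  if (length(x) == 0L) stop("at least one standard is required")
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyNA(names(x))) {
    stop("every standard needs a sample identifier")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate standard sample identifier: ",
         names(x)[duplicated(names(x))][1L])
  }
  x <- stats::setNames(as.numeric(x), names(x))
  if (any(!is.finite(x))) stop("standard amounts must be finite")
  structure(x, class = "standard_set")
}

#' @export
print.standard_set <- function(x, ...) {
  cat(sprintf("Standard set: %d standard(s)\n", length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Control parameters for calibration fits
#'
#' @param intercept logical; when `TRUE` each batch has a free intercept
#'   \eqn{a_i} in addition to its slope \eqn{b_i}.  Set to `FALSE` when the
#'   instrument reads zero for zero analyte (e.g. background-corrected
#'   fluorescence), which halves the number of sensitivity coefficients and
#'   the number of standards each batch needs.
#' @param tol relative convergence tolerance of the one-step iteration: the
#'   fit stops when every parameter changes by less than this fraction
#'   between successive iterations.
#' @param max_iter maximum number of one-step iterations before the fit
#'   aborts with an error.
#' @param outlier_sd residual threshold, in units of the estimated
#'   measurement standard deviation, beyond which [remove_outliers()]
#'   discards a measurement.
#' @param bounds optional named list with any of `a`, `b`, `x`, each a
#'   length-2 numeric range.  During the one-step iteration a parameter whose
#'   update leaves its range is clamped to the nearest endpoint (and freed
#'   again if a later update re-enters the range).  Useful to forbid, say,
#'   negative analyte amounts or near-zero slopes.
#' @param max_outlier_rounds cap on fit/flag/refit rounds in
#'   [remove_outliers()].
#' @return A list of class `"calib_control"`.
#' @export
calib_control <- function(intercept = TRUE, tol = 1e-5, max_iter = 10000L,
                          outlier_sd = 4, bounds = NULL,
                          max_outlier_rounds = 50L) {
  stopifnot(is.logical(intercept), length(intercept) == 1L, !is.na(intercept),
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1,
            is.numeric(outlier_sd), outlier_sd > 0,
            is.numeric(max_outlier_rounds), max_outlier_rounds >= 1)
  if (!is.null(bounds)) {
    if (!is.list(bounds) ||
        !all(names(bounds) %in% c("a", "b", "x")) ||
        !all(vapply(bounds, function(r) is.numeric(r) && length(r) == 2L &&
                      !anyNA(r) && r[1L] <= r[2L], logical(1L)))) {
      stop("'bounds' must be a named list of length-2 ranges for 'a', 'b' and/or 'x'")
    }
  }
  structure(
    list(intercept = intercept, tol = tol, max_iter = as.integer(max_iter),
         outlier_sd = outlier_sd, bounds = bounds,
         max_outlier_rounds = as.integer(max_outlier_rounds)),
    class = "calib_control")
}

# coerce user input (named vector / data frame) to the internal classes
as_measurement_table <- function(x) {
  if (inherits(x, "measurement_table")) x else measurement_table(x)
}

as_standard_set <- function(x) {
  if (inherits(x, "standard_set")) x else standard_set(x)
}

# number of sensitivity coefficients per batch under a control object
n_coef_per_batch <- function(control) if (control$intercept) 2L else 1L
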