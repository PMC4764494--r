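#' Per-batch sensitivity coefficients from standards (2-step calibration stage)
#'
#' Fits each batch's linear response \eqn{y = a_i + b_i x} by least squares
#' using only that batch's measurements of standard samples.  With a free
#' intercept,
#' \deqn{b_i = \frac{\langle x_j y_{ijk}\rangle - \langle x_j\rangle\langle y_{ijk}\rangle}
#'                  {\langle x_j^2\rangle - \langle x_j\rangle^2}, \qquad
#'       a_i = \langle y_{ijk}\rangle - b_i \langle x_j\rangle,}
#' with averages over the batch's standard measurements.  In the
#' zero-intercept model \eqn{a_i = 0} and
#' \eqn{b_i = \langle x_j y_{ijk}\rangle / \langle x_j^2\rangle}, which
#' weights each measurement by \eqn{x_j^2} — deliberately *not* the naive
#' average of \eqn{y_{ijk}/x_j}, which over-weights the small, noisy
#' measurements.
#'
#' @param table a [measurement_table()], already pruned with
#'   [prune_for_two_step()] so that every batch has enough distinct
#'   standards.
#' @param standards a [standard_set()].
#' @param control a [calib_control()].
#' @return A list with named numeric vectors `a` and `b`, one entry per
#'   batch.
#' @export
fit_batch_sensitivities <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  idx <- mt_index(table, standards)
  st <- batch_line_stats(idx, control$intercept)
  if (any(st$degenerate)) {
    stop("rank-deficient batch '", table$batches[which(st$degenerate)[1L]],
         "': its standards carry a single analyte amount but the intercept is free")
  }
  if (anyNA(st$b)) {
    stop("batch '", table$batches[which(is.na(st$b))[1L]],
         "' has too few distinct standard measurements; prune first ",
         "(see prune_for_two_step)")
  }
  list(a = stats::setNames(st$a, table$batches),
       b = stats::setNames(st$b, table$batches))
}

#' Analyte amounts from calibrated sensitivities (2-step prediction stage)
#'
#' Inverts the response model for every non-standard sample, pooling all of
#' the sample's measurements across batches with the weighting that the
#' Gaussian-noise model demands:
#' \deqn{x_j = \frac{\langle b_i y_{ijk}\rangle - \langle a_i b_i\rangle}
#'                  {\langle b_i^2\rangle},}
#' averages over all measurements of sample \eqn{j}.  This equals the
#' least-squares minimizer of \eqn{\sum (y - a_i - b_i x)^2} over \eqn{x} and
#' emphasizes measurements from sensitive batches, unlike the naive mean of
#' \eqn{(y_{ijk} - a_i)/b_i}.  Standards are never re-estimated.
#'
#' @param table a [measurement_table()].
#' @param a,b named numeric vectors of batch sensitivities covering every
#'   batch in `table`.
#' @param standards a [standard_set()].
#' @return Named numeric vector of estimated analyte amounts for the
#'   non-standard samples in `table`.
#' @export
predict_amounts <- function(table, a, b, standards) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  miss <- setdiff(table$batches, intersect(names(a), names(b)))
  if (length(miss) > 0L) {
    stop("no sensitivity estimates for batch '", miss[1L], "'")
  }
  am <- as.numeric(a[table$batch])
  bm <- as.numeric(b[table$batch])
  sj <- match(table$sample, table$samples)
  NS <- length(table$samples)
  s <- gsum(cbind(bm * table$value - am * bm, bm * bm), sj, NS)
  is_std <- table$samples %in% names(standards)
  target <- which(!is_std)
  den <- s[target, 2L]
  if (any(den <= 0)) {
    stop("uncalibratable sample '", table$samples[target[den <= 0][1L]],
         "': zero sensitivity in every batch that measured it")
  }
  stats::setNames(s[target, 1L] / den, table$samples[target])
}

# full 2-step pipeline: prune, fit lines on standards, invert, diagnostics
fit_two_step <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  pr <- prune_for_two_step(table, standards, control)
  tab <- pr$table
  sens <- fit_batch_sensitivities(tab, standards, control)
  x_unknown <- predict_amounts(tab, sens$a, sens$b, standards)
  x <- numeric(length(tab$samples))
  names(x) <- tab$samples
  is_std <- tab$samples %in% names(standards)
  x[is_std] <- as.numeric(unclass(standards)[tab$samples[is_std]])
  x[names(x_unknown)] <- x_unknown
  new_calibration(tab, standards, control,
                  a = as.numeric(sens$a), b = as.numeric(sens$b), x = x,
                  method = "two_step", iterations = 0L, trace = NULL,
                  removed = pr)
}
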