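#' Measurement-noise standard deviation of a calibration fit
#'
#' The rms deviation of the measurements from their fitted expectations
#' \eqn{a_i + b_i x_j}, with a degrees-of-freedom correction:
#' \deqn{\sigma = \sqrt{\frac{\sum_{ijk} (y_{ijk} - a_i - b_i x_j)^2}
#'                           {n_{All,All} - 2N_B - N_S}},}
#' where the denominator drops to \eqn{n_{All,All} - N_B - N_S} in the
#' zero-intercept model.  All measurements, standards included, enter the
#' sum.  Under the model about 68% of measurements should fall within one
#' \eqn{\sigma} of their expectations; much larger residuals flag outliers
#' (see [remove_outliers()]).
#'
#' @param fit a `"calibration"` object from [calibrate()].
#' @return The noise SD estimate (single numeric, in measurement units).
#' @export
estimate_sigma <- function(fit) {
  stopifnot(inherits(fit, "calibration"))
  if (fit$dof <= 0L) {
    stop("underdetermined: ", fit$n_used, " measurements cannot constrain ",
         fit$n_used - fit$dof, " parameters")
  }
  fit$sigma
}

#' Variability and precision of analyte-amount estimates
#'
#' Each non-standard amount estimate is a weighted mean over the sample's
#' measurements, so its spread is a weighted standard deviation:
#' \deqn{SD_j = \sqrt{\frac{n_{All,j}}{n_{All,j}-1} \cdot
#'   \frac{\langle (y_{ijk} - a_i - b_i x_j)^2 \rangle_{ik}}
#'        {\langle b_i^2 \rangle_{ik}}},}
#' and the precision of the estimate is \eqn{SE_j = SD_j / \sqrt{n_{All,j}}}.
#' The SE is a lower bound: it treats the fitted sensitivities as exact,
#' while in reality they carry uncertainty of their own.  Samples measured
#' once get `NA` (undefined, not zero); standards get `NA` because their
#' amounts are not estimates.
#'
#' @param fit a `"calibration"` object.
#' @return A data frame with one row per non-standard sample: `sample`,
#'   `x`, `n`, `sd`, `se`.
#' @export
sample_sd_se <- function(fit) {
  stopifnot(inherits(fit, "calibration"))
  tab <- fit$table
  is_std <- tab$samples %in% names(fit$standards)
  n_j <- tabulate(match(tab$sample, tab$samples), length(tab$samples))
  data.frame(sample = tab$samples[!is_std],
             x = as.numeric(fit$x[!is_std]),
             n = n_j[!is_std],
             sd = as.numeric(fit$sd_x[!is_std]),
             se = as.numeric(fit$se_x[!is_std]),
             stringsAsFactors = FALSE)
}

#' Variability and precision of batch sensitivity estimates
#'
#' Weighted standard deviations of the per-batch intercept and slope
#' estimates, from the spread of the batch's residuals:
#' \deqn{SD_{a_i} = \sqrt{\frac{n_{i,All}}{n_{i,All}-1}
#'         \langle (y_{ijk} - a_i - b_i x_j)^2 \rangle_{jk}}, \qquad
#'       SD_{b_i} = \sqrt{\frac{n_{i,All}}{n_{i,All}-1} \cdot
#'         \frac{\langle (y_{ijk} - a_i - b_i x_j)^2 \rangle_{jk}}
#'              {\langle x_j^2 \rangle_{jk}}}.}
#' Standard errors divide by \eqn{\sqrt{n_{i,All}}}.  Batches with a single
#' measurement get `NA`.
#'
#' @param fit a `"calibration"` object.
#' @return A data frame with one row per batch: `batch`, `a`, `b`, `n`,
#'   `sd_a`, `sd_b`, `se_a`, `se_b`.
#' @export
sensitivity_sds <- function(fit) {
  stopifnot(inherits(fit, "calibration"))
  tab <- fit$table
  n_i <- tabulate(match(tab$batch, tab$batches), length(tab$batches))
  data.frame(batch = tab$batches,
             a = as.numeric(fit$a), b = as.numeric(fit$b), n = n_i,
             sd_a = as.numeric(fit$sd_a), sd_b = as.numeric(fit$sd_b),
             se_a = as.numeric(fit$se_a), se_b = as.numeric(fit$se_b),
             stringsAsFactors = FALSE)
}

#' Iterative outlier removal with re-calibration
#'
#' Repeatedly fits the chosen calibration method, flags every measurement
#' whose residual is at least `control$outlier_sd` estimated standard
#' deviations from its expectation (default 4), removes all flagged
#' measurements at once, re-prunes, and refits, until a fit produces no
#' outliers.  Standards are screened like any other measurement — under the
#' one-step method even a batch's only standard can be flagged, because the
#' sensitivities do not hinge on it alone; under the two-step method with
#' minimal standards per batch this is impossible, since the line passes
#' through those points exactly.
#'
#' @param table a [measurement_table()].
#' @param standards a [standard_set()].
#' @param method `"one_step"` or `"two_step"`.
#' @param control a [calib_control()]; `outlier_sd` sets the threshold and
#'   `max_outlier_rounds` caps the loop.
#' @return A list of class `"outlier_report"`: `fit` (the final
#'   `"calibration"`), `table` (the cleaned [measurement_table()]), and
#'   `rounds`, a list of data frames (one per removal round) with columns
#'   `batch`, `sample`, `value`, `residual_sd`.
#' @export
remove_outliers <- function(table, standards, method = c("one_step", "two_step"),
                            control = calib_control()) {
  method <- match.arg(method)
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  rounds <- list()
  tab <- table
  for (round in seq_len(control$max_outlier_rounds)) {
    fit <- calibrate(tab, standards, method, control)
    sigma <- estimate_sigma(fit)
    r <- stats::residuals(fit)
    bad <- sigma > 0 & abs(r) >= control$outlier_sd * sigma
    if (!any(bad)) {
      return(structure(list(fit = fit, table = tab, rounds = rounds),
                       class = "outlier_report"))
    }
    # pruning only ever drops whole batches, so the fitted table's rows map
    # back to the working table by batch membership, in order
    kept_idx <- which(tab$batch %in% fit$table$batches)
    stopifnot(length(kept_idx) == n_measurements(fit$table))
    rounds[[round]] <- data.frame(
      batch = fit$table$batch[bad], sample = fit$table$sample[bad],
      value = fit$table$value[bad], residual_sd = r[bad] / sigma,
      stringsAsFactors = FALSE)
    drop <- rep(FALSE, n_measurements(tab))
    drop[kept_idx[bad]] <- TRUE
    tab <- mt_keep(tab, !drop)
  }
  cond <- structure(
    class = c("calibatch_outlier_loop", "error", "condition"),
    list(message = sprintf(
      "outlier removal did not stabilize within %d rounds",
      control$max_outlier_rounds),
      call = sys.call(), rounds = rounds))
  stop(cond)
}

#' @export
print.outlier_report <- function(x, ...) {
  n_rm <- sum(vapply(x$rounds, nrow, integer(1L)))
  cat(sprintf("Outlier report: %d measurement(s) removed in %d round(s)\n",
              n_rm, length(x$rounds)))
  print(x$fit)
  invisible(x)
}
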