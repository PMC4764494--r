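# One-step maximum likelihood calibration: all batch sensitivities and all
# unknown analyte amounts are fit to the entire data set at once.

#' Starting values for the one-step fit
#'
#' Batches with enough distinct standards of their own are initialized from
#' the per-batch standard regression (the 2-step calibration stage); the
#' remaining batches start from the mean of those estimates.  When no batch
#' has sufficient standards — calibration then rests entirely on shared
#' samples — all slopes start at 1 (intercepts at 0).  Unknown analyte
#' amounts start from the weighted inversion [predict_amounts()] under the
#' initial sensitivities.  The starting point only affects how fast the
#' iteration converges, not where it converges.
#'
#' @inheritParams fit_batch_sensitivities
#' @return A list with numeric vectors `a`, `b` (per batch, in table order)
#'   and `x` (per sample; standards carry their known amounts).
#' @export
initialize_one_step <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  idx <- mt_index(table, standards)
  st <- batch_line_stats(idx, control$intercept)
  a <- st$a
  b <- st$b
  a[st$degenerate] <- NA_real_
  b[st$degenerate] <- NA_real_
  if (all(is.na(b))) {
    b <- rep(1, idx$NB)
    a <- rep(0, idx$NB)
  } else {
    b[is.na(b)] <- mean(b, na.rm = TRUE)
    a[is.na(a)] <- if (control$intercept) mean(a, na.rm = TRUE) else 0
  }
  # initial amounts by weighted inversion under the starting sensitivities
  bm <- b[idx$bi]
  s <- gsum(cbind(bm * idx$y - a[idx$bi] * bm, bm * bm), idx$sj, idx$NS)
  x <- ifelse(s[, 2L] > 0, s[, 1L] / s[, 2L], NA_real_)
  x[!is.na(idx$known)] <- idx$known[!is.na(idx$known)]
  x[!is.finite(x)] <- mean(unclass(standards))
  list(a = stats::setNames(a, table$batches),
       b = stats::setNames(b, table$batches),
       x = stats::setNames(x, table$samples))
}

# full 1-step pipeline: orphan pruning, initialization, alternating
# minimization, diagnostics
fit_one_step <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  pr <- prune_orphans(table, standards, control)
  tab <- pr$table
  idx <- mt_index(tab, standards)
  init <- initialize_one_step(tab, standards, control)
  res <- one_step_core(idx, list(a = as.numeric(init$a), b = as.numeric(init$b),
                                 x = as.numeric(init$x)), control)
  new_calibration(tab, standards, control,
                  a = res$a, b = res$b, x = res$x,
                  method = "one_step", iterations = res$iterations,
                  trace = res$trace, removed = pr)
}

#' Calibrate a batch-structured measurement table
#'
#' Estimates batch-specific sensitivity coefficients and unknown analyte
#' amounts from raw measurements, under the linear Gaussian-noise response
#' model \eqn{y_{ijk} = \alpha_i + \beta_i x_j + \varepsilon_{ijk}} with
#' \eqn{\varepsilon_{ijk} \sim N(0, \sigma^2)}.
#'
#' Two methods are available:
#' \describe{
#'   \item{`"one_step"`}{Simultaneous maximum likelihood fit of all
#'     sensitivities and amounts by alternating minimization of the
#'     goodness-of-fit function
#'     \eqn{\chi^2 = \sum_{ijk} (y_{ijk} - a_i - b_i x_j)^2 / \sigma^2}.
#'     Each iteration first sets every unknown amount to its exact
#'     conditional minimizer, then refits every batch's line to *all* of its
#'     measurements (standards at their known amounts, other samples at
#'     their current estimates).  Because every substep is an exact
#'     coordinate minimization of a function that is quadratic with
#'     non-negative curvature in each parameter, \eqn{\chi^2} decreases
#'     monotonically and the iteration converges to the global minimum —
#'     the maximum likelihood predictors.  Samples replicated across batches
#'     cross-calibrate the batches, so batches without standards of their
#'     own remain usable as long as they are connected to standards through
#'     shared samples (see [prune_orphans()]).}
#'   \item{`"two_step"`}{The conventional approach: each batch's line is fit
#'     from its own standards only, then unknowns are obtained by weighted
#'     inversion (see [fit_batch_sensitivities()] and [predict_amounts()]).
#'     Batches without enough standards are dropped (see
#'     [prune_for_two_step()]).  Optimal when batches share no samples
#'     beyond a common standard, but wasteful otherwise.}
#' }
#'
#' The iteration stops when every parameter's relative change between
#' successive iterations falls below `control$tol` (default \eqn{10^{-5}});
#' relative change uses \eqn{|\Delta p| / \max(|p|, 10^{-12})} so that
#' parameters passing through zero remain well-defined.
#'
#' @param table a [measurement_table()] (or a data frame with columns
#'   `batch`, `sample`, `value`).
#' @param standards a [standard_set()] (or a named numeric vector).
#' @param method `"one_step"` (default) or `"two_step"`.
#' @param control a [calib_control()].
#' @return An object of class `"calibration"`, a list with components
#'   \describe{
#'     \item{`a`, `b`}{named sensitivity estimates per retained batch.}
#'     \item{`x`}{named analyte amounts per retained sample; standards carry
#'       their known amounts exactly.}
#'     \item{`sd_x`, `se_x`}{variability and precision of the amount
#'       estimates (`NA` for standards and for samples measured once).}
#'     \item{`sd_a`, `sd_b`, `se_a`, `se_b`}{per-batch sensitivity
#'       variabilities/precisions.}
#'     \item{`sigma`}{estimated measurement noise SD (rms residual with
#'       degrees-of-freedom correction).}
#'     \item{`chi2`}{residual sum of squares of the fit.}
#'     \item{`dof`}{residual degrees of freedom used for `sigma`.}
#'     \item{`iterations`, `trace`}{iteration count and per-iteration
#'       \eqn{\chi^2} / parameter-change trace (one-step only).}
#'     \item{`removed_batches`, `removed_samples`}{pruning provenance.}
#'     \item{`table`, `standards`, `control`, `method`}{the inputs actually
#'       used for the fit.}
#'   }
#' @examples
#' std <- standard_set(c(Std = 10))
#' mt <- measurement_table(
#'   batch  = rep(c("B1", "B2"), each = 4),
#'   sample = c("Std", "Std", "S1", "S2", "S1", "S2", "S3", "S3"),
#'   value  = c(20, 21, 10, 15, 5.2, 7.4, 12, 12.5))
#' fit <- calibrate(mt, std, method = "one_step",
#'                  control = calib_control(intercept = FALSE))
#' fit$x
#' @export
calibrate <- function(table, standards, method = c("one_step", "two_step"),
                      control = calib_control()) {
  method <- match.arg(method)
  if (method == "one_step") {
    fit_one_step(table, standards, control)
  } else {
    fit_two_step(table, standards, control)
  }
}

# assemble the full result object, including all per-parameter diagnostics
new_calibration <- function(table, standards, control, a, b, x, method,
                            iterations, trace, removed) {
  idx <- mt_index(table, standards)
  names(a) <- names(b) <- table$batches
  names(x) <- table$samples
  resid <- idx$y - a[idx$bi] - b[idx$bi] * x[idx$sj]
  chi2 <- sum(resid * resid)
  n <- length(idx$y)
  dof <- n - n_coef_per_batch(control) * idx$NB - idx$NS
  sigma <- if (dof > 0) sqrt(chi2 / dof) else NA_real_

  n_j <- tabulate(idx$sj, idx$NS)
  n_i <- tabulate(idx$bi, idx$NB)
  is_std <- !is.na(idx$known)

  ms_j <- gsum(cbind(resid * resid, (b[idx$bi])^2), idx$sj, idx$NS) / n_j
  sd_x <- sqrt(n_j / (n_j - 1) * ms_j[, 1L] / ms_j[, 2L])
  sd_x[n_j < 2L] <- NA_real_
  se_x <- sd_x / sqrt(n_j)
  sd_x[is_std] <- NA_real_
  se_x[is_std] <- NA_real_
  names(sd_x) <- names(se_x) <- table$samples

  ms_i <- gsum(cbind(resid * resid, (x[idx$sj])^2), idx$bi, idx$NB) / n_i
  sd_a <- sqrt(n_i / (n_i - 1) * ms_i[, 1L])
  sd_b <- sqrt(n_i / (n_i - 1) * ms_i[, 1L] / ms_i[, 2L])
  sd_a[n_i < 2L] <- NA_real_
  sd_b[n_i < 2L] <- NA_real_
  se_a <- sd_a / sqrt(n_i)
  se_b <- sd_b / sqrt(n_i)
  names(sd_a) <- names(sd_b) <- names(se_a) <- names(se_b) <- table$batches

  structure(
    list(method = method, a = a, b = b, x = x,
         sd_x = sd_x, se_x = se_x,
         sd_a = sd_a, sd_b = sd_b, se_a = se_a, se_b = se_b,
         sigma = sigma, chi2 = chi2, dof = dof,
         n_used = n, iterations = iterations, trace = trace,
         removed_batches = removed$removed_batches,
         removed_samples = removed$removed_samples,
         table = table, standards = standards, control = control),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("%s calibration of %d measurements (%d batches, %d samples)\n",
              if (x$method == "one_step") "One-step" else "Two-step",
              x$n_used, length(x$a), length(x$x)))
  if (x$method == "one_step") {
    cat(sprintf("  converged in %d iterations\n", x$iterations))
  }
  cat(sprintf("  sigma = %.6g, chi2 = %.6g (dof = %d)\n",
              x$sigma, x$chi2, x$dof))
  if (nrow(x$removed_batches) > 0L || nrow(x$removed_samples) > 0L) {
    cat(sprintf("  pruned: %d batch(es), %d sample(s)\n",
                nrow(x$removed_batches), nrow(x$removed_samples)))
  }
  invisible(x)
}

#' @export
residuals.calibration <- function(object, ...) {
  tab <- object$table
  unname(tab$value - object$a[tab$batch] -
           object$b[tab$batch] * object$x[tab$sample])
}

#' @export
coef.calibration <- function(object, ...) {
  list(a = object$a, b = object$b, x = object$x)
}
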