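#' Replicate simulation study comparing the two calibration methods
#'
#' Generates `n_replicates` datasets from a [design_spec()], calibrates each
#' with both the one-step and two-step methods (each with its own pruning
#' rule), and aggregates parameter-recovery statistics:
#'
#' \itemize{
#'   \item mean signed relative error (bias) and rms relative error of the
#'     unknown analyte amounts, in percent;
#'   \item rms relative errors of the intercept and slope sensitivities;
#'   \item mean of the per-replicate measurement-noise SD estimates (which
#'     should approach the generating noise SD for a well-fitting method);
#'   \item the ratio of the mean estimated standard error to the rms actual
#'     deviation of the amount estimates from truth (an SE-calibration
#'     check; values below 100% reflect that the SE is a lower bound);
#'   \item the fraction of batches pruned by each method.
#' }
#'
#' Relative error is (estimate - truth)/truth.  To keep the method
#' comparison symmetric, a parameter enters the error statistics only if it
#' was estimated by *both* methods (not pruned away by either) and both
#' estimates are less than 2-fold away from the truth, in the sense
#' |estimate - truth| < |truth| (estimate within (0, 2 truth)); the rare
#' wild estimates would otherwise dominate the rms.  Errors are pooled
#' across replicates before averaging.  Noise-SD means use all successful
#' fits, without exclusions.
#'
#' @param spec a [design_spec()] or preset name.
#' @param n_replicates number of datasets to generate and fit.
#' @param seed integer; replicate `r` uses seed `seed + r`.
#' @return An object of class `"validation_summary"`: a list with `stats`
#'   (data frame of the statistics above, one column per method),
#'   `n_replicates`, `n_failed`, `n_excluded` (counts excluded by the 2-fold
#'   rule, per parameter), `n_unmeasured` (unknown samples that drew no
#'   measurement), and `spec`.
#' @examples
#' \donttest{
#' summ <- run_study(design_preset("default"), n_replicates = 50, seed = 1)
#' summ
#' }
#' @export
run_study <- function(spec, n_replicates, seed = 1L) {
  if (is.character(spec)) spec <- design_preset(spec)
  stopifnot(inherits(spec, "design_spec"), n_replicates >= 1L)
  n_replicates <- as.integer(n_replicates)
  control <- calib_control(intercept = spec$intercept)

  acc <- list(x = list(), a = list(), b = list())
  sigma1 <- sigma2 <- rep(NA_real_, n_replicates)
  removed1 <- removed2 <- 0L
  total_batches <- 0L
  n_failed <- 0L
  n_unmeasured <- 0L

  for (r in seq_len(n_replicates)) {
    ds <- generate_dataset(spec, seed = seed + r)
    truth <- ds$truth
    f1 <- try(calibrate(ds$table, truth$standards, "one_step", control),
              silent = TRUE)
    f2 <- try(calibrate(ds$table, truth$standards, "two_step", control),
              silent = TRUE)
    if (inherits(f1, "try-error") || inherits(f2, "try-error")) {
      n_failed <- n_failed + 1L
      next
    }
    unk <- setdiff(names(truth$x_true), names(truth$standards))
    n_unmeasured <- n_unmeasured + sum(!unk %in% ds$table$samples)

    acc$x[[r]] <- data.frame(
      truth = as.numeric(truth$x_true[unk]),
      est1 = as.numeric(f1$x[unk]), est2 = as.numeric(f2$x[unk]),
      se1 = as.numeric(f1$se_x[unk]), se2 = as.numeric(f2$se_x[unk]))
    bt <- names(truth$beta)
    acc$a[[r]] <- data.frame(truth = as.numeric(truth$alpha[bt]),
                             est1 = as.numeric(f1$a[bt]),
                             est2 = as.numeric(f2$a[bt]),
                             se1 = NA_real_, se2 = NA_real_)
    acc$b[[r]] <- data.frame(truth = as.numeric(truth$beta[bt]),
                             est1 = as.numeric(f1$b[bt]),
                             est2 = as.numeric(f2$b[bt]),
                             se1 = NA_real_, se2 = NA_real_)
    sigma1[r] <- f1$sigma
    sigma2[r] <- f2$sigma
    removed1 <- removed1 + nrow(f1$removed_batches)
    removed2 <- removed2 + nrow(f2$removed_batches)
    total_batches <- total_batches + spec$n_batches
  }

  pool <- lapply(acc, function(lst) do.call(rbind, lst))
  xs <- pooled_errors(pool$x)
  as <- if (spec$intercept) pooled_errors(pool$a) else NULL
  bs <- pooled_errors(pool$b)

  stats <- data.frame(
    statistic = c("bias_x_pct", "rms_x_pct", "rms_a_pct", "rms_b_pct",
                  "mean_sigma", "se_ratio_pct", "pct_batches_removed"),
    one_step = c(xs$bias1, xs$rms1,
                 if (is.null(as)) NA_real_ else as$rms1, bs$rms1,
                 mean(sigma1, na.rm = TRUE), xs$se_ratio1,
                 100 * removed1 / total_batches),
    two_step = c(xs$bias2, xs$rms2,
                 if (is.null(as)) NA_real_ else as$rms2, bs$rms2,
                 mean(sigma2, na.rm = TRUE), xs$se_ratio2,
                 100 * removed2 / total_batches),
    stringsAsFactors = FALSE)

  structure(
    list(stats = stats, n_replicates = n_replicates, n_failed = n_failed,
         n_excluded = c(x = xs$n_excluded,
                        a = if (is.null(as)) 0L else as$n_excluded,
                        b = bs$n_excluded),
         n_unmeasured = n_unmeasured, spec = spec),
    class = "validation_summary")
}

# pooled bias / rms / SE-calibration statistics under the symmetric 2-fold
# inclusion rule
pooled_errors <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(list(bias1 = NA_real_, bias2 = NA_real_, rms1 = NA_real_,
                rms2 = NA_real_, se_ratio1 = NA_real_, se_ratio2 = NA_real_,
                n_excluded = 0L))
  }
  estimated <- is.finite(df$est1) & is.finite(df$est2) & df$truth != 0
  r1 <- df$est1 / df$truth
  r2 <- df$est2 / df$truth
  within2 <- estimated & r1 > 0 & r1 < 2 & r2 > 0 & r2 < 2
  n_excluded <- sum(estimated & !within2)
  rel1 <- r1[within2] - 1
  rel2 <- r2[within2] - 1
  dev1 <- df$est1[within2] - df$truth[within2]
  dev2 <- df$est2[within2] - df$truth[within2]
  se_ratio <- function(se, dev) {
    ok <- is.finite(se)
    if (!any(ok)) return(NA_real_)
    100 * mean(se[ok]) / sqrt(mean(dev[ok]^2))
  }
  list(bias1 = 100 * mean(rel1), bias2 = 100 * mean(rel2),
       rms1 = 100 * sqrt(mean(rel1^2)), rms2 = 100 * sqrt(mean(rel2^2)),
       se_ratio1 = se_ratio(df$se1[within2], dev1),
       se_ratio2 = se_ratio(df$se2[within2], dev2),
       n_excluded = n_excluded)
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Validation study: %d replicate(s) of design '%s'%s\n",
              x$n_replicates, x$spec$assignment,
              if (x$n_failed > 0L) sprintf(" (%d failed)", x$n_failed) else ""))
  out <- x$stats
  out$one_step <- signif(out$one_step, 4)
  out$two_step <- signif(out$two_step, 4)
  print(out, row.names = FALSE)
  if (sum(x$n_excluded) > 0L) {
    cat(sprintf("  excluded by 2-fold rule: x=%d, a=%d, b=%d\n",
                x$n_excluded[["x"]], x$n_excluded[["a"]], x$n_excluded[["b"]]))
  }
  invisible(x)
}

#' @export
as.data.frame.validation_summary <- function(x, ...) x$stats
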