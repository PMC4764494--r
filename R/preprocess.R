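#' Remove batches that cannot be calibrated
#'
#' The two methods have different minimum-information requirements, and each
#' gets its own pruning rule.
#'
#' `prune_for_two_step()` applies the classical rule: a batch can only be
#' calibrated from its own standards, so it must contain at least as many
#' distinct measured standards as it has unknown sensitivity coefficients
#' (two with a free intercept, one without).  Batches falling short are
#' removed, and samples measured nowhere else are removed with them.
#'
#' `prune_orphans()` applies the weaker one-step requirement: a batch only
#' needs to be *connected* to enough standards, directly or through chains of
#' shared samples, because shared samples let batches cross-calibrate each
#' other.  Concretely, the bipartite batch-sample graph (an edge wherever
#' \eqn{n_{ij} \ge 1}) is decomposed into connected components and a batch is
#' retained iff its component contains at least as many distinct measured
#' standards as there are sensitivity coefficients per batch.  Everything in
#' a failing component is an orphan and is removed.  Component-level counting
#' is a deliberate simplification of "independent connections": it covers the
#' practical layouts, and genuinely rank-deficient layouts that slip through
#' are caught by the fitters' degenerate-batch checks.
#'
#' Both functions iterate until the kept table is stable, and both are
#' idempotent.  `prune_orphans()` always keeps a (weak) superset of the
#' batches kept by `prune_for_two_step()`.
#'
#' @param table a [measurement_table()].
#' @param standards a [standard_set()].
#' @param control a [calib_control()]; only `intercept` is consulted.
#' @return A list of class `"prune_report"` with elements `table` (the kept
#'   [measurement_table()]), `removed_batches` and `removed_samples` (data
#'   frames with columns `id` and `reason`).
#' @examples
#' mt <- measurement_table(
#'   batch  = c("B1", "B1", "B2", "B2", "B3"),
#'   sample = c("Std", "S2", "S2", "S3", "S4"),
#'   value  = c(5, 8, 9, 3, 7))
#' std <- standard_set(c(Std = 1))
#' ctl <- calib_control(intercept = FALSE)
#' # B2 has no standard but shares S2 with B1, so the one-step rule keeps it;
#' # B3 is isolated and is an orphan under both rules.
#' prune_orphans(mt, std, ctl)$table
#' prune_for_two_step(mt, std, ctl)$table
#' @export
prune_for_two_step <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  need <- n_coef_per_batch(control)

  removed_b <- character(0)
  removed_s <- character(0)
  repeat {
    is_std <- table$sample %in% names(standards)
    n_distinct_std <- vapply(
      table$batches,
      function(b) length(unique(table$sample[is_std & table$batch == b])),
      integer(1L))
    drop_b <- table$batches[n_distinct_std < need]
    if (length(drop_b) == 0L) break
    removed_b <- c(removed_b, drop_b)
    keep <- !(table$batch %in% drop_b)
    if (!any(keep)) {
      stop("no calibratable batches: every batch lacks sufficient standard measurements")
    }
    lost_s <- setdiff(table$samples, unique(table$sample[keep]))
    removed_s <- c(removed_s, lost_s)
    table <- mt_keep(table, keep)
  }
  prune_report(table, removed_b, removed_s,
               sprintf("fewer than %d distinct measured standards", need),
               "only measured in removed batches")
}

#' @rdname prune_for_two_step
#' @export
prune_orphans <- function(table, standards, control = calib_control()) {
  table <- as_measurement_table(table)
  standards <- as_standard_set(standards)
  need <- n_coef_per_batch(control)

  removed_b <- character(0)
  removed_s <- character(0)
  repeat {
    comp <- batch_sample_components(table)
    measured_std <- intersect(names(standards), table$samples)
    # distinct measured standards available in each component
    std_comp <- comp$sample[match(measured_std, names(comp$sample))]
    n_std <- vapply(seq_len(comp$n),
                    function(cc) sum(std_comp == cc, na.rm = TRUE),
                    integer(1L))
    bad_comp <- which(n_std < need)
    if (length(bad_comp) == 0L) break
    drop_b <- names(comp$batch)[comp$batch %in% bad_comp]
    drop_s <- names(comp$sample)[comp$sample %in% bad_comp]
    removed_b <- c(removed_b, drop_b)
    removed_s <- c(removed_s, drop_s)
    keep <- !(table$batch %in% drop_b)
    if (!any(keep)) {
      stop("no connection to standards: every batch is an orphan")
    }
    table <- mt_keep(table, keep)
  }
  prune_report(table, removed_b, removed_s,
               "component not connected to enough distinct standards",
               "component not connected to enough distinct standards")
}

# connected components of the bipartite batch-sample graph
batch_sample_components <- function(table) {
  bv <- paste0("B\r", table$batches)
  sv <- paste0("S\r", table$samples)
  edges <- unique(data.frame(b = paste0("B\r", table$batch),
                             s = paste0("S\r", table$sample),
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = c(bv, sv)))
  memb <- igraph::components(g)$membership
  list(batch = stats::setNames(as.integer(memb[bv]), table$batches),
       sample = stats::setNames(as.integer(memb[sv]), table$samples),
       n = max(memb))
}

prune_report <- function(table, removed_b, removed_s, reason_b, reason_s) {
  structure(
    list(table = table,
         removed_batches = data.frame(id = removed_b,
                                      reason = rep_len(reason_b, length(removed_b)),
                                      stringsAsFactors = FALSE),
         removed_samples = data.frame(id = removed_s,
                                      reason = rep_len(reason_s, length(removed_s)),
                                      stringsAsFactors = FALSE)),
    class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat(sprintf("Prune report: kept %d measurements, %d batches, %d samples\n",
              n_measurements(x$table), length(x$table$batches),
              length(x$table$samples)))
  cat(sprintf("  removed: %d batch(es), %d sample(s)\n",
              nrow(x$removed_batches), nrow(x$removed_samples)))
  invisible(x)
}
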