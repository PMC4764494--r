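# Internal numeric core shared by the two fitting methods.
#
# All fitting works on an index structure: measurement values y with integer
# batch indices bi (1..NB) and sample indices sj (1..NS), plus the vector of
# known analyte amounts (NA for unknown samples).  Group sums are computed
# with rowsum(), which keeps a full one-step iteration at two C-level passes
# over the data.

mt_index <- function(table, standards) {
  structure(
    list(y = table$value,
         bi = match(table$batch, table$batches),
         sj = match(table$sample, table$samples),
         NB = length(table$batches),
         NS = length(table$samples),
         known = as.numeric(unclass(standards)[table$samples])),
    sample_names = table$samples, batch_names = table$batches)
}

# group sums over groups 1..n; absent groups contribute 0
gsum <- function(v, g, n) {
  tmp <- rowsum(v, g)
  if (is.null(dim(v))) v <- cbind(v)
  out <- matrix(0, n, ncol(v))
  out[as.integer(rownames(tmp)), ] <- tmp
  out
}

# Per-batch least-squares line through the standard measurements only
# (the calibration stage of the 2-step method).  Returns a and b vectors of
# length NB with NA where a batch has too few distinct standards, and
# degenerate = TRUE where the standards are present but carry no amount
# variation (rank-deficient with a free intercept).
batch_line_stats <- function(idx, intercept) {
  xs <- idx$known[idx$sj]
  sel <- !is.na(xs)
  need <- if (intercept) 2L else 1L
  NB <- idx$NB
  a <- b <- rep(NA_real_, NB)
  degenerate <- rep(FALSE, NB)
  if (!any(sel)) {
    return(list(a = a, b = b, degenerate = degenerate,
                n_distinct = integer(NB)))
  }
  ys <- idx$y[sel]
  xss <- xs[sel]
  bis <- idx$bi[sel]
  sjs <- idx$sj[sel]
  n_iT <- tabulate(bis, NB)
  n_distinct <- vapply(seq_len(NB),
                       function(i) length(unique(sjs[bis == i])),
                       integer(1L))
  ok <- n_distinct >= need
  s <- gsum(cbind(ys, xss, xss * ys, xss * xss), bis, NB)
  my <- s[, 1L] / n_iT
  mx <- s[, 2L] / n_iT
  mxy <- s[, 3L] / n_iT
  mx2 <- s[, 4L] / n_iT
  if (intercept) {
    den <- mx2 - mx * mx
    degenerate <- ok & (den <= .Machine$double.eps * pmax(mx2, 1))
    use <- ok & !degenerate
    b[use] <- (mxy[use] - mx[use] * my[use]) / den[use]
    a[use] <- my[use] - b[use] * mx[use]
  } else {
    degenerate <- ok & (mx2 <= 0)
    use <- ok & !degenerate
    b[use] <- mxy[use] / mx2[use]
    a[use] <- 0
  }
  list(a = a, b = b, degenerate = degenerate, n_distinct = n_distinct)
}

clamp_range <- function(v, range) pmin(pmax(v, range[1L]), range[2L])

# Alternating coordinate minimization of the goodness-of-fit function
# sum_ijk (y_ijk - a_i - b_i x_j)^2.  Each pass first replaces every unknown
# analyte amount by its exact 1-D minimizer given the current sensitivities,
# then every (a_i, b_i) pair by its exact per-batch least-squares line given
# the current amounts; both substeps solve their subproblem exactly, so the
# objective can only decrease (absent bound clamping).
one_step_core <- function(idx, init, control) {
  y <- idx$y
  bi <- idx$bi
  sj <- idx$sj
  NB <- idx$NB
  NS <- idx$NS
  known <- idx$known
  unknown <- which(is.na(known))
  intercept <- control$intercept
  bounds <- control$bounds
  eps_abs <- 1e-12

  a <- init$a
  b <- init$b
  x <- ifelse(is.na(known), init$x, known)
  ni <- tabulate(bi, NB)

  chi2_trace <- numeric(0)
  delta_trace <- numeric(0)
  clamp_events <- data.frame(iteration = integer(0), parameter = character(0),
                             bound = numeric(0), stringsAsFactors = FALSE)
  note_clamp <- function(it, par, v, range) {
    hit <- v < range[1L] | v > range[2L]
    if (any(hit)) {
      clamp_events <<- rbind(clamp_events, data.frame(
        iteration = it, parameter = rep(par, sum(hit)),
        bound = ifelse(v[hit] < range[1L], range[1L], range[2L]),
        stringsAsFactors = FALSE))
    }
  }

  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    a_old <- a
    b_old <- b
    x_old <- x

    # analyte-amount update (unknown samples only; standards stay fixed)
    bb <- b[bi]
    s <- gsum(cbind(bb * y - a[bi] * bb, bb * bb), sj, NS)
    if (length(unknown) > 0L) {
      den <- s[unknown, 2L]
      if (any(den <= 0)) {
        stop("uncalibratable sample: all sensitivities are zero for sample '",
             idx_sample_name(idx, unknown[den <= 0][1L]), "'")
      }
      xnew <- s[unknown, 1L] / den
      if (!is.null(bounds$x)) {
        note_clamp(it, "x", xnew, bounds$x)
        xnew <- clamp_range(xnew, bounds$x)
      }
      x[unknown] <- xnew
    }

    # sensitivity update, one exact least-squares line per batch
    xm <- x[sj]
    s <- gsum(cbind(y, xm, xm * y, xm * xm), bi, NB)
    my <- s[, 1L] / ni
    mx <- s[, 2L] / ni
    mxy <- s[, 3L] / ni
    mx2 <- s[, 4L] / ni
    if (intercept) {
      den <- mx2 - mx * mx
      bad <- den <= .Machine$double.eps * pmax(mx2, 1)
      if (any(bad)) {
        stop("degenerate batch: no analyte-amount variation within batch ",
             which(bad)[1L])
      }
      b <- (mxy - mx * my) / den
      if (!is.null(bounds$b)) {
        note_clamp(it, "b", b, bounds$b)
        b <- clamp_range(b, bounds$b)
      }
      a <- my - b * mx
      if (!is.null(bounds$a)) {
        note_clamp(it, "a", a, bounds$a)
        a <- clamp_range(a, bounds$a)
      }
    } else {
      if (any(mx2 <= 0)) {
        stop("degenerate batch: all analyte amounts zero within batch ",
             which(mx2 <= 0)[1L])
      }
      b <- mxy / mx2
      if (!is.null(bounds$b)) {
        note_clamp(it, "b", b, bounds$b)
        b <- clamp_range(b, bounds$b)
      }
      a <- rep(0, NB)
    }

    chi2_trace[it] <- sum((y - a[bi] - b[bi] * x[sj])^2)
    rel <- c(abs(a - a_old) / pmax(abs(a_old), eps_abs),
             abs(b - b_old) / pmax(abs(b_old), eps_abs),
             abs(x[unknown] - x_old[unknown]) / pmax(abs(x_old[unknown]), eps_abs))
    delta_trace[it] <- if (length(rel) > 0L) max(rel) else 0
    if (delta_trace[it] < control$tol) {
      converged <- TRUE
      break
    }
  }

  trace <- list(chi2 = chi2_trace, max_rel_change = delta_trace,
                clamp_events = clamp_events)
  if (!converged) {
    cond <- structure(
      class = c("calibatch_no_convergence", "error", "condition"),
      list(message = sprintf(
        "one-step fit did not converge in %d iterations (last max relative change %.3g)",
        control$max_iter, delta_trace[it]),
        call = sys.call(-1L), trace = trace))
    stop(cond)
  }
  list(a = a, b = b, x = x, iterations = it, trace = trace)
}

idx_sample_name <- function(idx, j) {
  # indices were built with match() against table$samples; recover the label
  attr(idx, "sample_names")[j] %||% as.character(j)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
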