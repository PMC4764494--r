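# Independent oracles and fixture builders shared across the test files.

# Generic numerical minimizer of the goodness-of-fit function
# sum_ijk (y - a_i - b_i x_j)^2 over (a, b, x_unknown), written directly from
# the objective with its analytic gradient and solved with nlminb.  It shares
# no code with the alternating-update fitter.
oracle_min_chi2 <- function(table, standards, intercept = TRUE) {
  bi <- match(table$batch, table$batches)
  sj <- match(table$sample, table$samples)
  NB <- length(table$batches)
  NS <- length(table$samples)
  known <- as.numeric(unclass(standards)[table$samples])
  unk <- which(is.na(known))
  nu <- length(unk)
  y <- table$value
  na <- if (intercept) NB else 0L

  unpack <- function(p) {
    a <- if (intercept) p[seq_len(NB)] else rep(0, NB)
    b <- p[na + seq_len(NB)]
    x <- known
    x[unk] <- p[na + NB + seq_len(nu)]
    list(a = a, b = b, x = x)
  }
  obj <- function(p) {
    q <- unpack(p)
    sum((y - q$a[bi] - q$b[bi] * q$x[sj])^2)
  }
  grad <- function(p) {
    q <- unpack(p)
    r <- y - q$a[bi] - q$b[bi] * q$x[sj]
    ga <- -2 * rowsum(r, bi)[, 1L]
    gb <- -2 * rowsum(r * q$x[sj], bi)[, 1L]
    gx <- numeric(NS)
    gs <- -2 * rowsum(r * q$b[bi], sj)
    gx[as.integer(rownames(gs))] <- gs[, 1L]
    c(if (intercept) ga, gb, gx[unk])
  }
  start <- c(if (intercept) rep(0, NB), rep(1, NB),
             rep(mean(known, na.rm = TRUE), nu))
  fit <- stats::nlminb(start, obj, grad,
                       control = list(iter.max = 10000, eval.max = 20000,
                                      rel.tol = 1e-15, x.tol = 1e-14))
  fit$objective
}

# small well-connected random instance with known truth
random_instance <- function(seed, n_batches = 3, n_unknowns = 4,
                            n_measurements = 30, noise_sd = 0.3,
                            intercept = TRUE) {
  spec <- design_spec(
    standard_amounts = c(1, 3), n_unknowns = n_unknowns,
    unknown_mean = 2, unknown_sd = 0.5,
    n_batches = n_batches, alpha_mean = if (intercept) 1 else 0,
    alpha_sd = if (intercept) 0.3 else 0,
    beta_mean = 2, beta_sd = 0.4,
    n_measurements = n_measurements, noise_sd = noise_sd,
    assignment = "every_batch_every_standard", intercept = intercept)
  generate_dataset(spec, seed = seed)
}

# random sparse batch/sample table (no model structure; for count identities)
random_raw_table <- function(seed) {
  set.seed(seed)
  n <- sample(1:60, 1)
  measurement_table(
    batch = sprintf("b%d", sample.int(6, n, replace = TRUE)),
    sample = sprintf("s%d", sample.int(8, n, replace = TRUE)),
    value = stats::rnorm(n))
}

expect_chi2_monotone <- function(fit) {
  ch <- fit$trace$chi2
  expect_true(all(diff(ch) <= 1e-9 * (1 + ch[-length(ch)])))
}
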