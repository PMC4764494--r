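#' Specify a synthetic batch-calibration design
#'
#' Describes the generating process for artificial measurement tables with
#' known ground truth: true analyte amounts for a handful of standards plus a
#' Gaussian population of unknowns, Gaussian batch sensitivities, an
#' assignment scheme placing measurements on (batch, sample) pairs, and
#' additive Gaussian measurement noise
#' (\eqn{y_{ijk} = \alpha_i + \beta_i x_j + \varepsilon_{ijk}}).
#'
#' The defaults are the reference validation design: standards at amounts 5
#' and 15, 18 unknown samples with amounts ~ N(10, 3), 20 batches with
#' intercepts ~ N(100, 30) and slopes ~ N(10, 3), and 400 measurements at
#' uniformly random (batch, sample) pairs with noise SD 20.
#'
#' Assignment schemes:
#' \describe{
#'   \item{`uniform_random`}{every measurement lands on an independently
#'     uniform (batch, sample) pair, with replacement.}
#'   \item{`every_batch_every_standard`}{one measurement of each standard is
#'     forced into every batch; the rest are uniform.}
#'   \item{`common_standard_only`}{a designed layout: a single common
#'     standard plus one private unknown per batch, batches sharing nothing
#'     but the standard; measurements are divided equally over batches and,
#'     within each batch, split evenly between the standard and the private
#'     unknown (requires `n_unknowns == n_batches` and one standard).}
#'   \item{`common_standard_plus_one`}{as above plus one additional unknown
#'     sample shared by every batch (the first unknown; per-batch
#'     measurements cycle standard/shared/private; requires
#'     `n_unknowns == n_batches + 1`).}
#'   \item{`every_batch_every_sample`}{the full factorial layout, each pair
#'     measured exactly once (`n_measurements` must equal
#'     `n_batches * (length(standard_amounts) + n_unknowns)`).}
#' }
#'
#' `scale_factor` and `negate` rescale the whole problem (amounts,
#' intercepts and noise; slopes are dimensionless in this scaling), for
#' exercising fitters far from the default magnitudes.
#'
#' @param standard_amounts known analyte amounts of the standards.
#' @param n_unknowns number of unknown samples.
#' @param unknown_mean,unknown_sd Gaussian population of true unknown
#'   amounts.
#' @param n_batches number of batches.
#' @param alpha_mean,alpha_sd Gaussian population of true batch intercepts.
#' @param beta_mean,beta_sd Gaussian population of true batch slopes.
#' @param n_measurements total number of measurements per dataset.
#' @param noise_sd measurement noise SD (instrument units).
#' @param assignment one of the schemes above.
#' @param intercept whether fits of this design should estimate intercepts;
#'   set `FALSE` together with `alpha_mean = alpha_sd = 0`.
#' @param scale_factor multiply all amounts, intercepts and noise by this.
#' @param negate additionally flip the sign (equivalent to a negative
#'   `scale_factor`).
#' @return A list of class `"design_spec"`.
#' @seealso [design_preset()] for the named ready-made designs,
#'   [generate_dataset()] to draw data.
#' @export
design_spec <- function(standard_amounts = c(5, 15),
                        n_unknowns = 18, unknown_mean = 10, unknown_sd = 3,
                        n_batches = 20, alpha_mean = 100, alpha_sd = 30,
                        beta_mean = 10, beta_sd = 3,
                        n_measurements = 400, noise_sd = 20,
                        assignment = c("uniform_random",
                                       "every_batch_every_standard",
                                       "common_standard_only",
                                       "common_standard_plus_one",
                                       "every_batch_every_sample"),
                        intercept = TRUE,
                        scale_factor = 1, negate = FALSE) {
  assignment <- match.arg(assignment)
  stopifnot(length(standard_amounts) >= 1L, all(is.finite(standard_amounts)),
            n_unknowns >= 1L, n_batches >= 1L, n_measurements >= 1L,
            unknown_sd >= 0, alpha_sd >= 0, beta_sd >= 0, noise_sd >= 0,
            is.finite(scale_factor), scale_factor != 0,
            is.logical(intercept), is.logical(negate))
  n_samples <- length(standard_amounts) + n_unknowns
  if (assignment == "common_standard_only") {
    if (length(standard_amounts) != 1L || n_unknowns != n_batches) {
      stop("common_standard_only needs one standard and n_unknowns == n_batches")
    }
  }
  if (assignment == "common_standard_plus_one") {
    if (length(standard_amounts) != 1L || n_unknowns != n_batches + 1L) {
      stop("common_standard_plus_one needs one standard and n_unknowns == n_batches + 1")
    }
  }
  if (assignment == "every_batch_every_standard" &&
      n_measurements < n_batches * length(standard_amounts)) {
    stop("not enough measurements to place every standard in every batch")
  }
  if (assignment == "every_batch_every_sample" &&
      n_measurements != n_batches * n_samples) {
    stop("every_batch_every_sample needs n_measurements == n_batches * n_samples")
  }
  structure(
    list(standard_amounts = as.numeric(standard_amounts),
         n_unknowns = as.integer(n_unknowns),
         unknown_mean = unknown_mean, unknown_sd = unknown_sd,
         n_batches = as.integer(n_batches),
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         beta_mean = beta_mean, beta_sd = beta_sd,
         n_measurements = as.integer(n_measurements), noise_sd = noise_sd,
         assignment = assignment, intercept = intercept,
         scale_factor = scale_factor * if (negate) -1 else 1),
    class = "design_spec")
}

#' Ready-made synthetic designs
#'
#' Named presets covering the reference validation design and its variants:
#' \describe{
#'   \item{`default`}{the default [design_spec()].}
#'   \item{`all_standards`}{both standards forced into every batch.}
#'   \item{`common_standard_only`}{zero-intercept; 10 batches each holding
#'     the single common standard (amount 10) and one private unknown; 100
#'     measurements.  Batches share no samples beyond the standard, so the
#'     one-step and two-step methods coincide exactly on these data.}
#'   \item{`common_standard_plus_one`}{as above plus one unknown sample
#'     shared by every batch, the minimal design in which cross-batch
#'     sharing starts to pay off.}
#'   \item{`full_factorial`}{every batch measures every sample once; noise
#'     SD 10.}
#'   \item{`noise_half`, `noise_double`}{default design at noise SD 10 and
#'     40.}
#'   \item{`scale_up100`, `scale_down100`, `negated`}{default design with
#'     all true values 100-fold larger, 100-fold smaller, or negated.}
#' }
#'
#' @param name preset name.
#' @return A `"design_spec"`.
#' @export
design_preset <- function(name = c("default", "all_standards",
                                   "common_standard_only",
                                   "common_standard_plus_one",
                                   "full_factorial",
                                   "noise_half", "noise_double",
                                   "scale_up100", "scale_down100", "negated")) {
  name <- match.arg(name)
  switch(name,
    default = design_spec(),
    all_standards = design_spec(assignment = "every_batch_every_standard"),
    common_standard_only = design_spec(
      standard_amounts = 10, n_unknowns = 10, n_batches = 10,
      n_measurements = 100, alpha_mean = 0, alpha_sd = 0,
      intercept = FALSE, assignment = "common_standard_only"),
    common_standard_plus_one = design_spec(
      standard_amounts = 10, n_unknowns = 11, n_batches = 10,
      n_measurements = 100, alpha_mean = 0, alpha_sd = 0,
      intercept = FALSE, assignment = "common_standard_plus_one"),
    full_factorial = design_spec(assignment = "every_batch_every_sample",
                                 noise_sd = 10),
    noise_half = design_spec(noise_sd = 10),
    noise_double = design_spec(noise_sd = 40),
    scale_up100 = design_spec(scale_factor = 100),
    scale_down100 = design_spec(scale_factor = 0.01),
    negated = design_spec(negate = TRUE))
}

#' Generate a synthetic measurement table with known truth
#'
#' Draws true unknown amounts, batch sensitivities, a measurement layout and
#' Gaussian noise according to a [design_spec()], then evaluates the response
#' model to produce the raw measurements.  Reproducible: the same `seed`
#' yields bit-identical data.  All random quantities are drawn at the base
#' scale and then multiplied by the design's scale factor, so scaled and
#' negated designs are exactly equivariant copies of the base design under
#' the same seed.
#'
#' @param spec a [design_spec()] or preset name for [design_preset()].
#' @param seed integer seed.
#' @return A list with elements `table` (a [measurement_table()]) and
#'   `truth`, itself a list with named vectors `alpha`, `beta`, `x_true`,
#'   the effective `noise_sd`, and the `standards` [standard_set()].
#' @examples
#' ds <- generate_dataset(design_preset("default"), seed = 1)
#' ds$table
#' fit <- calibrate(ds$table, ds$truth$standards)
#' cor(fit$x, ds$truth$x_true[names(fit$x)])
#' @export
generate_dataset <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- design_preset(spec)
  stopifnot(inherits(spec, "design_spec"))
  if (!is.null(seed)) set.seed(seed)

  n_std <- length(spec$standard_amounts)
  NS <- n_std + spec$n_unknowns
  NB <- spec$n_batches
  std_names <- sprintf("Std%d", seq_len(n_std))
  unk_names <- sprintf("U%02d", seq_len(spec$n_unknowns))
  batch_names <- sprintf("B%02d", seq_len(NB))

  x_unknown <- stats::rnorm(spec$n_unknowns, spec$unknown_mean, spec$unknown_sd)
  alpha <- stats::rnorm(NB, spec$alpha_mean, spec$alpha_sd)
  beta <- stats::rnorm(NB, spec$beta_mean, spec$beta_sd)
  lay <- assignment_layout(spec, NB, NS, n_std)
  eps <- stats::rnorm(spec$n_measurements, 0, spec$noise_sd)

  f <- spec$scale_factor
  x_true <- c(spec$standard_amounts, x_unknown) * f
  names(x_true) <- c(std_names, unk_names)
  alpha <- alpha * f
  eps <- eps * f

  y <- alpha[lay$bi] + beta[lay$bi] * x_true[lay$sj] + eps
  list(table = measurement_table(batch_names[lay$bi],
                                 names(x_true)[lay$sj], unname(y)),
       truth = list(alpha = stats::setNames(alpha, batch_names),
                    beta = stats::setNames(beta, batch_names),
                    x_true = x_true,
                    noise_sd = abs(f) * spec$noise_sd,
                    standards = standard_set(stats::setNames(
                      spec$standard_amounts * f, std_names)),
                    spec = spec))
}

# integer (batch, sample) index pairs for each assignment scheme; samples are
# indexed standards-first (1..n_std), then unknowns
assignment_layout <- function(spec, NB, NS, n_std) {
  n <- spec$n_measurements
  switch(spec$assignment,
    uniform_random = list(bi = sample.int(NB, n, replace = TRUE),
                          sj = sample.int(NS, n, replace = TRUE)),
    every_batch_every_standard = {
      fixed_b <- rep(seq_len(NB), each = n_std)
      fixed_s <- rep(seq_len(n_std), times = NB)
      n_rest <- n - length(fixed_b)
      list(bi = c(fixed_b, sample.int(NB, n_rest, replace = TRUE)),
           sj = c(fixed_s, sample.int(NS, n_rest, replace = TRUE)))
    },
    common_standard_only = balanced_layout(
      NB, n, function(b, nb) rep_len(c(1L, 1L + b), nb)),
    common_standard_plus_one =
      # one measurement of the shared sample per batch; the rest of the
      # batch's lanes split evenly between the standard and its private
      # unknown, mirroring the common-standard-only layout
      balanced_layout(
        NB, n, function(b, nb) c(2L, rep_len(c(1L, 2L + b), nb - 1L))),
    every_batch_every_sample = list(bi = rep(seq_len(NB), each = NS),
                                    sj = rep(seq_len(NS), times = NB)))
}

# deterministic designed layout: measurements are divided equally over the
# batches; fn(b, nb) returns the nb sample indices laid out in batch b
balanced_layout <- function(NB, n, fn) {
  per_batch <- rep(n %/% NB, NB) + (seq_len(NB) <= n %% NB)
  bi <- rep(seq_len(NB), times = per_batch)
  sj <- unlist(lapply(seq_len(NB), function(b) fn(b, per_batch[b])),
               use.names = FALSE)
  list(bi = bi, sj = sj)
}
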