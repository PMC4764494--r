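test_that("initialization uses per-batch standard fits, means for the rest, or all ones", {
  ctl <- calib_control(intercept = FALSE)
  std <- standard_set(c(Std = 2))
  # every batch has the standard: initialization equals the two-step fit
  mt <- measurement_table(c("B1", "B1", "B2", "B2"),
                          c("Std", "U1", "Std", "U1"), c(4, 3, 8, 5))
  init <- initialize_one_step(mt, std, ctl)
  sens <- fit_batch_sensitivities(mt, std, ctl)
  expect_equal(init$b, sens$b)
  # no batch has a standard (connected via shared sample): all slopes start at 1
  mt2 <- measurement_table(c("B1", "B1", "B2", "B2"),
                           c("U1", "U2", "U2", "U3"), c(1, 2, 3, 4))
  init2 <- initialize_one_step(mt2, standard_set(c(Zed = 1)), ctl)
  expect_equal(unname(init2$b), c(1, 1))
  # mixed: batches without standards start from the mean of the fitted slopes
  mt3 <- measurement_table(c("B1", "B1", "B2", "B2", "B3", "B3"),
                           c("Std", "U1", "Std", "U1", "U1", "U2"),
                           c(4, 3, 8, 5, 2, 1))
  init3 <- initialize_one_step(mt3, std, ctl)
  expect_equal(unname(init3$b["B3"]),
               mean(c(init3$b[["B1"]], init3$b[["B2"]])))
})

test_that("with a common standard and no shared samples the two methods coincide", {
  ctl <- calib_control(intercept = FALSE, tol = 1e-10)
  ds <- generate_dataset(design_preset("common_standard_only"), seed = 5)
  f1 <- calibrate(ds$table, ds$truth$standards, "one_step", ctl)
  f2 <- calibrate(ds$table, ds$truth$standards, "two_step", ctl)
  expect_equal(f1$x, f2$x, tolerance = 1e-6)
  expect_equal(f1$b, f2$b, tolerance = 1e-6)
  expect_equal(f1$sigma, f2$sigma, tolerance = 1e-6)
})

test_that("noise-free data are recovered exactly with zero chi-squared", {
  spec <- design_spec(noise_sd = 0, n_measurements = 200)
  ds <- generate_dataset(spec, seed = 3)
  fit <- calibrate(ds$table, ds$truth$standards, "one_step",
                   calib_control(tol = 1e-10))
  expect_lt(fit$chi2, 1e-8)
  expect_lt(fit$sigma, 1e-4)
  expect_equal(fit$a, ds$truth$alpha[names(fit$a)], tolerance = 1e-6)
  expect_equal(fit$b, ds$truth$beta[names(fit$b)], tolerance = 1e-6)
  expect_equal(fit$x, ds$truth$x_true[names(fit$x)], tolerance = 1e-6)
})

test_that("chi-squared decreases monotonically and convergence is fast", {
  for (seed in 1:10) {
    ds <- random_instance(seed, noise_sd = 0.5)
    fit <- calibrate(ds$table, ds$truth$standards, "one_step")
    expect_chi2_monotone(fit)
    expect_lte(fit$iterations, 2000)
  }
})

test_that("the alternating fit reaches the optimum of a generic minimizer", {
  for (seed in 1:12) {
    intercept <- seed %% 2 == 0
    ds <- random_instance(seed, noise_sd = 0.4, intercept = intercept)
    ctl <- calib_control(intercept = intercept, tol = 1e-12)
    fit <- calibrate(ds$table, ds$truth$standards, "one_step", ctl)
    ora <- oracle_min_chi2(fit$table, ds$truth$standards, intercept = intercept)
    expect_equal(fit$chi2, ora, tolerance = 1e-8)
  }
})

test_that("pinning an unknown as the reference only changes the gauge", {
  # no true standard: assign the role to sample U1 at two different amounts
  set.seed(9)
  batch <- sprintf("B%d", sample.int(4, 40, replace = TRUE))
  sampl <- sprintf("U%d", sample.int(5, 40, replace = TRUE))
  y <- abs(rnorm(40, 50, 10))
  mt <- measurement_table(batch, sampl, y)
  ctl <- calib_control(intercept = FALSE, tol = 1e-10)
  f1 <- calibrate(mt, standard_set(c(U1 = 1)), "one_step", ctl)
  f3 <- calibrate(mt, standard_set(c(U1 = 3)), "one_step", ctl)
  expect_equal(f3$x, 3 * f1$x, tolerance = 1e-6)
  expect_equal(f3$b, f1$b / 3, tolerance = 1e-6)
  expect_equal(f3$chi2, f1$chi2, tolerance = 1e-8)
})

test_that("parameter bounds clamp updates and are re-tested each iteration", {
  ds <- random_instance(11, noise_sd = 0.3)
  free <- calibrate(ds$table, ds$truth$standards, "one_step")
  lo <- max(free$b) * 1.05  # force every slope against the lower bound
  ctl <- calib_control(bounds = list(b = c(lo, lo * 10)))
  fit <- calibrate(ds$table, ds$truth$standards, "one_step", ctl)
  expect_true(all(fit$b >= lo - 1e-12))
  expect_gt(nrow(fit$trace$clamp_events), 0)
  expect_gte(fit$chi2, free$chi2)
})

test_that("hitting the iteration cap raises a condition that carries the trace", {
  ds <- random_instance(2, noise_sd = 0.5)
  ctl <- calib_control(tol = 1e-13, max_iter = 3L)
  err <- tryCatch(calibrate(ds$table, ds$truth$standards, "one_step", ctl),
                  calibatch_no_convergence = function(e) e)
  expect_s3_class(err, "calibatch_no_convergence")
  expect_length(err$trace$chi2, 3L)
})
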