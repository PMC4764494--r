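test_that("zero-intercept slope uses amount-squared weighting, not the naive ratio mean", {
  ctl <- calib_control(intercept = FALSE)
  std <- standard_set(c(S1 = 1, S2 = 2))
  mt <- measurement_table(c("B1", "B1"), c("S1", "S2"), c(2, 4))
  sens <- fit_batch_sensitivities(mt, std, ctl)
  expect_equal(unname(sens$b["B1"]), (1 * 2 + 2 * 4) / (1 + 4))  # = 2
  expect_equal(unname(sens$a["B1"]), 0)

  # replicated single standard: weighted answer is 3, naive mean of y/x too
  # (they coincide at x = 1) but the weighting matters for the estimator form
  mt2 <- measurement_table(c("B1", "B1"), c("S1", "S1"), c(2, 4))
  sens2 <- fit_batch_sensitivities(mt2, standard_set(c(S1 = 1)), ctl)
  expect_equal(unname(sens2$b["B1"]), 3)

  # x = 2 replicated: Eq-8 weighting gives sum(xy)/sum(x^2) = 12/8, while the
  # naive mean of y/x would give 1.5 as well here; use unequal x to separate
  mt3 <- measurement_table(c("B1", "B1"), c("S1", "S2"), c(3, 2))
  std3 <- standard_set(c(S1 = 1, S2 = 4))
  sens3 <- fit_batch_sensitivities(mt3, std3, ctl)
  expect_equal(unname(sens3$b["B1"]), (1 * 3 + 4 * 2) / (1 + 16))
  naive <- mean(c(3 / 1, 2 / 4))
  expect_false(isTRUE(all.equal(unname(sens3$b["B1"]), naive)))
})

test_that("noise-free sensitivities and amounts are recovered exactly", {
  std <- standard_set(c(S1 = 1, S2 = 4))
  x <- c(S1 = 1, S2 = 4, U1 = 2.5, U2 = 3.2)
  alpha <- c(B1 = 3, B2 = -1)
  beta <- c(B1 = 7, B2 = 5)
  batch <- rep(c("B1", "B2"), each = 4)
  sampl <- rep(names(x), 2)
  mt <- measurement_table(batch, sampl, alpha[batch] + beta[batch] * x[sampl])
  fit <- calibrate(mt, std, "two_step")
  expect_equal(fit$a, alpha)
  expect_equal(fit$b, beta)
  expect_equal(fit$x[c("U1", "U2")], x[c("U1", "U2")])
  expect_equal(fit$chi2, 0)
  expect_equal(unname(fit$x[names(std)]), as.numeric(std))
})

test_that("amount prediction is the weighted inversion over all analyses", {
  std <- standard_set(c(S = 1))
  # single measurement in a batch with a = 0, b = 2
  a <- c(B1 = 0); b <- c(B1 = 2)
  mt <- measurement_table("B1", "U1", 6)
  expect_equal(predict_amounts(mt, a, b, std), c(U1 = 3))
  # two batches, b = {1, 2}, a = 0, y = {1, 4}
  mt2 <- measurement_table(c("B1", "B2"), c("U1", "U1"), c(1, 4))
  expect_equal(predict_amounts(mt2, c(B1 = 0, B2 = 0), c(B1 = 1, B2 = 2), std),
               c(U1 = 9 / 5))
  # standards are never re-estimated
  mt3 <- measurement_table(c("B1", "B1"), c("S", "U1"), c(2, 6))
  expect_identical(names(predict_amounts(mt3, a, b, std)), "U1")
})

test_that("the weighted inversion minimizes the per-sample least squares", {
  for (seed in 1:15) {
    set.seed(seed)
    k <- sample(2:6, 1)
    a <- rnorm(k)
    b <- rnorm(k, 2, 0.5)
    y <- rnorm(k, 5, 2)
    mt <- measurement_table(sprintf("B%d", 1:k), rep("U", k), y)
    names(a) <- names(b) <- mt$batches
    xhat <- predict_amounts(mt, a, b, standard_set(c(S = 1)))
    brute <- stats::optimize(function(x) sum((y - a - b * x)^2),
                             interval = c(-100, 100), tol = 1e-10)$minimum
    expect_equal(unname(xhat), brute, tolerance = 1e-6)
  }
})

test_that("two-step calibration is scale equivariant", {
  ds <- random_instance(42)
  std <- ds$truth$standards
  fit <- calibrate(ds$table, std, "two_step")
  # scaling all measurements scales sensitivities, not amounts
  tab_c <- measurement_table(ds$table$batch, ds$table$sample, ds$table$value * 7)
  fit_c <- calibrate(tab_c, std, "two_step")
  expect_equal(fit_c$a, 7 * fit$a)
  expect_equal(fit_c$b, 7 * fit$b)
  expect_equal(fit_c$x, fit$x)
  # scaling the standard amounts scales amounts and divides slopes
  std_c <- standard_set(stats::setNames(as.numeric(std) * 5, names(std)))
  fit_s <- calibrate(ds$table, std_c, "two_step")
  expect_equal(fit_s$b, fit$b / 5)
  expect_equal(fit_s$x, fit$x * 5)
})

test_that("rank-deficient batches are reported", {
  std <- standard_set(c(S1 = 2, S2 = 2))
  mt <- measurement_table(c("B1", "B1"), c("S1", "S2"), c(1, 2))
  expect_error(fit_batch_sensitivities(mt, std, calib_control(intercept = TRUE)),
               "rank-deficient")
})
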