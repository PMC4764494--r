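test_that("the noise SD is the dof-corrected rms residual", {
  # crafted so the fitted line passes through the two group means exactly,
  # leaving hand-known residuals {1, -1, 0, 2, -2}; dof = 5 - 2*1 - 2 = 1
  std <- standard_set(c(S0 = 0, S1 = 1))
  a <- 4; b <- 3
  mt <- measurement_table(
    batch = rep("B1", 5),
    sample = c("S0", "S0", "S0", "S1", "S1"),
    value = c(a + 1, a - 1, a, a + b + 2, a + b - 2))
  fit <- calibrate(mt, std, "two_step")
  expect_equal(unname(fit$a), a)
  expect_equal(unname(fit$b), b)
  expect_equal(sort(residuals(fit)), sort(c(1, -1, 0, 2, -2)))
  expect_identical(fit$dof, 1L)
  expect_equal(estimate_sigma(fit), sqrt(10 / 1))
})

test_that("sigma estimation refuses underdetermined fits", {
  std <- standard_set(c(S0 = 0, S1 = 1))
  mt <- measurement_table(rep("B1", 3), c("S0", "S1", "U1"), c(0, 1, 2))
  fit <- calibrate(mt, std, "two_step")
  expect_true(is.na(fit$sigma))
  expect_error(estimate_sigma(fit), "underdetermined")
})

test_that("amount SD reduces to the ordinary sample SD when all slopes are 1", {
  ctl <- calib_control(intercept = FALSE)
  std <- standard_set(c(S = 10))
  mt <- measurement_table(
    batch = c("B1", "B1", "B1"),
    sample = c("S", "U1", "U1"),
    value = c(10, 4, 6))
  fit <- calibrate(mt, std, "two_step", ctl)
  expect_equal(unname(fit$b), 1)
  tabl <- sample_sd_se(fit)
  expect_equal(tabl$sd[tabl$sample == "U1"], stats::sd(c(4, 6)))
  expect_equal(tabl$se[tabl$sample == "U1"], stats::sd(c(4, 6)) / sqrt(2))

  # two identical replicates have zero spread
  mt2 <- measurement_table(c("B1", "B1", "B1"), c("S", "U1", "U1"),
                           c(10, 5, 5))
  fit2 <- calibrate(mt2, std, "two_step", ctl)
  expect_equal(sample_sd_se(fit2)$sd, 0)

  # a sample measured once is flagged undefined, not zero
  mt3 <- measurement_table(c("B1", "B1"), c("S", "U1"), c(10, 5))
  fit3 <- calibrate(mt3, std, "two_step", ctl)
  expect_true(is.na(sample_sd_se(fit3)$sd))
  expect_true(is.na(sample_sd_se(fit3)$se))
})

test_that("SE never exceeds SD and both are non-negative on random fits", {
  for (seed in 1:10) {
    ds <- random_instance(seed, n_measurements = 40, noise_sd = 0.4)
    for (m in c("one_step", "two_step")) {
      fit <- calibrate(ds$table, ds$truth$standards, m)
      tabl <- sample_sd_se(fit)
      ok <- !is.na(tabl$sd)
      expect_true(all(tabl$sd[ok] >= 0))
      expect_true(all(tabl$se[ok] <= tabl$sd[ok] + 1e-12))
      if (!is.na(fit$sigma)) expect_gte(fit$sigma, 0)
    }
  }
})

test_that("sensitivity SDs match the generic weighted-SD computation", {
  ds <- random_instance(21, n_measurements = 36, noise_sd = 0.5)
  fit <- calibrate(ds$table, ds$truth$standards, "one_step")
  tabl <- sensitivity_sds(fit)
  tab <- fit$table
  r <- residuals(fit)
  for (i in seq_along(tab$batches)) {
    sel <- tab$batch == tab$batches[i]
    n <- sum(sel)
    x <- fit$x[tab$sample[sel]]
    # weighted SD (weights x^2) of the per-point slope estimates
    z <- (tab$value[sel] - fit$a[tab$batches[i]]) / x
    w <- x^2
    sd_b_oracle <- sqrt(n * sum(w * (z - fit$b[tab$batches[i]])^2) /
                          ((n - 1) * sum(w)))
    expect_equal(tabl$sd_b[i], unname(sd_b_oracle), tolerance = 1e-8)
    sd_a_oracle <- sqrt(sum(r[sel]^2) / (n - 1))
    expect_equal(tabl$sd_a[i], unname(sd_a_oracle), tolerance = 1e-8)
    expect_equal(tabl$se_b[i], tabl$sd_b[i] / sqrt(n))
  }
  # noise-free fits have zero sensitivity spread
  ds0 <- random_instance(22, noise_sd = 0)
  fit0 <- calibrate(ds0$table, ds0$truth$standards, "one_step",
                    calib_control(tol = 1e-10))
  expect_true(all(sensitivity_sds(fit0)$sd_a < 1e-6))
  expect_true(all(sensitivity_sds(fit0)$sd_b < 1e-6))
})

test_that("planted gross outliers are found and removed; clean data are untouched", {
  spec <- design_spec(n_measurements = 300)
  ds <- generate_dataset(spec, seed = 17)
  std <- ds$truth$standards
  clean <- remove_outliers(ds$table, std, "one_step")
  expect_length(clean$rounds, 0)
  expect_identical(n_measurements(clean$table), n_measurements(ds$table))

  # offset one measurement by 10 true noise SDs
  tab <- as.data.frame(ds$table)
  tab$value[137] <- tab$value[137] + 10 * ds$truth$noise_sd
  rep1 <- remove_outliers(measurement_table(tab), std, "one_step")
  removed <- do.call(rbind, rep1$rounds)
  hit <- removed$batch == tab$batch[137] & removed$sample == tab$sample[137] &
    removed$value == tab$value[137]
  expect_identical(sum(hit), 1L)
  expect_gte(abs(removed$residual_sd[hit]), 4)
  expect_identical(n_measurements(rep1$table),
                   n_measurements(ds$table) - nrow(removed))
  expect_lte(nrow(removed), 3L)
})

test_that("a corrupted standard measurement is detectable by the one-step loop", {
  # each batch holds its minimal standard set, so the two-step line passes
  # through the standards and cannot flag them; the one-step fit can
  ds <- generate_dataset(design_preset("common_standard_only"), seed = 23)
  std <- ds$truth$standards
  tab <- as.data.frame(ds$table)
  i_std <- which(tab$sample == names(std)[1])[3]
  tab$value[i_std] <- tab$value[i_std] + 12 * ds$truth$noise_sd
  ctl <- calib_control(intercept = FALSE)
  rep1 <- remove_outliers(measurement_table(tab), std, "one_step", ctl)
  removed <- do.call(rbind, rep1$rounds)
  expect_true(names(std)[1] %in% removed$sample)
})
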