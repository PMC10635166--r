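test_that("zero dose leaves every cell alive in both arms", {
  fit <- flash_spheroid(flash_params(dose = 0, S_ROD = 160),
                        cell_params("tumor"), survival_params(kr = 0),
                        include_ros = FALSE, n_r = 50)
  expect_equal(fit$overall_sf_conv, 1)
  expect_equal(fit$overall_sf_flash, 1)
  expect_true(all(fit$log10_sf_conv == 0))
})

test_that("FLASH survival dominates CONV pointwise and in aggregate", {
  for (cfg in list(list(cell = "tumor", S = 160, ros = FALSE),
                   list(cell = "healthy", S = 15.3, ros = TRUE))) {
    sp <- if (cfg$ros) survival_params() else survival_params(kr = 0)
    fit <- flash_spheroid(flash_params(S_ROD = cfg$S),
                          cell_params(cfg$cell), sp,
                          include_ros = cfg$ros, n_r = 120)
    expect_true(all(fit$log10_sf_flash >= fit$log10_sf_conv - 1e-12))
    expect_gte(fit$overall_sf_flash, fit$overall_sf_conv)
    expect_true(all(fit$log10_sf_conv <= 0))
    expect_true(fit$overall_sf_conv > 0 && fit$overall_sf_conv <= 1)
  }
})

test_that("inside the anoxic core the two arms coincide when ROS is off", {
  fit <- flash_spheroid(flash_params(S_ROD = 160),
                        cell_params("tumor"), survival_params(kr = 0),
                        include_ros = FALSE, n_r = 200)
  core <- fit$r_mm < fit$profile$r0_mm
  expect_true(any(core))
  expect_true(all(abs(fit$log10_sf_flash[core] -
                      fit$log10_sf_conv[core]) <= 1e-12))
})

test_that("FLASH converges to CONV as the depletion rate vanishes", {
  sp <- survival_params(kr = 0)
  ps <- 35
  target <- conv_log_survival(ps, 10, sp)
  gaps <- vapply(c(16, 4, 1, 0.25, 0.0625, 0.015625), function(S)
    abs(flash_log_survival(ps, 10, 90, S, sp, include_ros = FALSE) - target),
    numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 1e-3)
})

test_that("with the depletion-only model the log-survival gap grows with dose", {
  sp <- survival_params(kr = 0)
  gap <- vapply(c(5, 10, 15, 20), function(D) {
    fit <- flash_spheroid(flash_params(S_ROD = 160, dose = D),
                          cell_params("tumor"), sp, include_ros = FALSE,
                          n_r = 150)
    log10(fit$overall_sf_flash) - log10(fit$overall_sf_conv)
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("healthy tissue gains a larger FLASH sparing ratio than tumor", {
  sp <- survival_params()
  h <- flash_spheroid(flash_params(S_ROD = 15.3), cell_params("healthy"),
                      sp, n_r = 150)
  t <- flash_spheroid(flash_params(S_ROD = 15.3), cell_params("tumor"),
                      sp, n_r = 150)
  expect_gt(h$overall_sf_flash / h$overall_sf_conv,
            t$overall_sf_flash / t$overall_sf_conv)
  # healthy cells also keep a smaller anoxic core (lower metabolism)
  expect_lt(h$profile$r0_mm, t$profile$r0_mm)
})

test_that("summary and data-frame views expose the aggregate quantities", {
  fit <- flash_spheroid(flash_params(S_ROD = 15.3), cell_params("healthy"),
                        survival_params(), n_r = 60)
  s <- summary(fit)
  expect_equal(s$sf_ratio_flash_conv,
               fit$overall_sf_flash / fit$overall_sf_conv)
  df <- as.data.frame(fit)
  expect_named(df, c("r_mm", "ps_mmHg", "log10_sf_conv", "log10_sf_flash"))
  expect_equal(nrow(df), 60)
  expect_output(print(fit), "overall SF")
  expect_output(print(s), "FLASH/CONV SF ratio")
})
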