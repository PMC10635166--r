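sp0 <- survival_params()

test_that("OER has the anoxic value 1, saturation m, and half-point (m+1)/2", {
  expect_equal(oer(0, sp0), 1)
  expect_equal(oer(1e12, sp0), 2.6, tolerance = 1e-10)
  expect_equal(oer(1.9, sp0), (2.6 + 1) / 2)
  expect_true(all(diff(oer(seq(0, 200, by = 0.5), sp0)) > 0))
  expect_error(oer(-1, sp0), "non-negative")
  # inverse orientation flips the direction for sensitivity analysis
  spi <- survival_params(oer_orientation = "inverse")
  expect_equal(oer(0, spi), 2.6)
  expect_equal(oer(1e12, spi), 1, tolerance = 1e-10)
})

test_that("LQ coefficients scale as OER and OER squared", {
  lq <- lq_coefficients(0, sp0)
  expect_equal(lq$alpha, 0.44)
  expect_equal(lq$beta, 0.44)
  lqs <- lq_coefficients(1e12, sp0)
  expect_equal(lqs$alpha, 0.44 * 2.6, tolerance = 1e-10)
  expect_equal(lqs$beta, 0.44 * 2.6^2, tolerance = 1e-10)
  # square law: wherever OER doubles, beta quadruples
  p2 <- 1.9 / (2.6 - 2)                     # solves OER(p) = 2
  expect_equal(oer(p2, sp0), 2)
  expect_equal(lq_coefficients(p2, sp0)$beta / 0.44, 4)
})

test_that("conventional closed form reproduces hand-computed values", {
  expect_equal(conv_log_survival(50, 0, sp0), 0)
  expect_equal(conv_log_survival(0, 10, sp0), -(0.44 * 10 + 0.44 * 100))
  o <- oer(20, sp0)
  expect_equal(conv_log_survival(20, 5, sp0),
               -0.44 * o * 5 - 0.44 * o^2 * 25)
})

test_that("FLASH integral collapses to the conventional form without depletion", {
  set.seed(11)
  for (i in 1:25) {
    ps <- runif(1, 0, 160); dose <- runif(1, 1, 20)
    ddot <- runif(1, 0.05, 150)
    sp <- survival_params(alpha0 = runif(1, 0.1, 0.6),
                          beta0 = runif(1, 0.01, 0.6),
                          m = runif(1, 1.5, 3.5), K = runif(1, 0.5, 5),
                          kr = 0)
    expect_lt(abs(flash_log_survival(ps, dose, ddot, 0, sp,
                                     include_ros = FALSE) -
                  conv_log_survival(ps, dose, sp)), 1e-10)
  }
})

test_that("quadrature matches the piecewise-analytic antiderivative", {
  draws <- lhs_draw(60, survival_ranges, seed = 13L)
  worst <- 0
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    q <- flash_log_survival(d$ps, d$dose, d$dose_rate, d$S_ROD, sp0,
                            include_ros = FALSE)
    a <- flash_log_survival_analytic(d$ps, d$dose, d$dose_rate, d$S_ROD, sp0)
    worst <- max(worst, abs(q - a) / abs(a))
  }
  expect_lt(worst, 1e-8)
})

test_that("the oxidative-stress sigmoid is tiny at zero and saturates at kr", {
  y0 <- oxidative_relief(0, sp0)
  expect_equal(y0, 3e-2 / (1 + exp(8)))
  expect_lt(y0, 2e-5)
  expect_equal(oxidative_relief(-1, sp0), 3e-2, tolerance = 1e-4)
  grid <- seq(-0.1, 0.1, length.out = 101)
  expect_true(all(diff(oxidative_relief(grid, sp0)) < 0))
})

test_that("depletion and ROS relief both raise FLASH survival", {
  cell <- cell_params("healthy")
  ln_conv <- conv_log_survival(30, 10, sp0)
  ln_rod <- flash_log_survival(30, 10, 90, 160, sp0, include_ros = FALSE)
  ln_full <- flash_log_survival(30, 10, 90, 160, sp0, cell = cell)
  expect_gt(ln_rod, ln_conv)
  expect_gt(ln_full, ln_rod)
  expect_lte(ln_full, 0)
})

test_that("the ROS term requires cell parameters", {
  expect_error(flash_log_survival(30, 10, 90, 160, sp0), "cell")
})

test_that("anoxic radii cannot distinguish FLASH from CONV when ROS is off", {
  spk0 <- survival_params(kr = 0)
  for (d in c(5, 10, 20))
    expect_lt(abs(flash_log_survival(0, d, 90, 160, spk0,
                                     include_ros = FALSE) -
                  conv_log_survival(0, d, spk0)), 1e-12)
})
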