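test_that("tricube weights match the closed form", {
  expect_equal(tricube_weight(0, 5), 1)
  expect_equal(tricube_weight(5, 5), 0)
  expect_equal(tricube_weight(2.5, 5), (1 - 1 / 8)^3)  # 0.669921875
  expect_error(tricube_weight(1, 0), "positive")
})

test_that("periodic LOESS reproduces constants to numerical precision", {
  f <- loess_periodic(rep(2.5, 80), smoothing_params(frac = 0.2))
  expect_lt(max(abs(f$fitted - 2.5)), 1e-9)
})

test_that("periodic LOESS equals the naive per-point oracle", {
  set.seed(1)
  n <- 120
  y <- 1 + 0.3 * sin(2 * pi * (0:(n - 1)) / n) + rnorm(n, 0, 0.05)
  # unmasked (regular-grid) path
  f1 <- loess_periodic(y, smoothing_params(frac = 0.1))
  expect_lt(max(abs(f1$fitted - naive_periodic_loess(y, rep(TRUE, n), 12))),
            1e-9)
  # odd window size
  f2 <- loess_periodic(y, smoothing_params(frac = 0.125))
  expect_lt(max(abs(f2$fitted - naive_periodic_loess(y, rep(TRUE, n), 15))),
            1e-9)
  # masked (irregular) path, including evaluation at masked bins
  use <- rep(TRUE, n); use[c(5, 40:45, 118)] <- FALSE
  ym <- y; ym[!use] <- NA
  f3 <- loess_periodic(mfa_profile(ym, 1), smoothing_params(frac = 0.1))
  expect_lt(max(abs(f3$fitted -
                      naive_periodic_loess(y, use, round(0.1 * sum(use))))),
            1e-9)
})

test_that("periodic LOESS matches a generic LOESS on tripled data", {
  set.seed(2)
  n <- 150
  y <- 2 + cos(2 * pi * (0:(n - 1)) / n) + rnorm(n, 0, 0.1)
  f <- loess_periodic(y, smoothing_params(frac = 0.1))
  expect_lt(max(abs(f$fitted - tiled_loess_oracle(y, 0.1))), 1e-6)
})

test_that("the fit is equivariant under rotation of the circle", {
  set.seed(3)
  n <- 100
  y <- 1 + 0.5 * sin(2 * pi * (0:(n - 1)) / n)^2 + rnorm(n, 0, 0.02)
  f0 <- loess_periodic(y, smoothing_params(frac = 0.15))$fitted
  for (r in c(13, 50)) {
    yr <- y[((0:(n - 1) + r) %% n) + 1]
    fr <- loess_periodic(yr, smoothing_params(frac = 0.15))$fitted
    expect_lt(max(abs(fr[(((0:(n - 1)) - r) %% n) + 1] - f0)), 1e-9)
  }
})

test_that("a local quadratic is reproduced exactly inside its region", {
  n <- 200
  i <- 0:(n - 1)
  y <- 1 + 0.002 * (i - 100)^2            # quadratic except at the wrap
  f <- loess_periodic(y, smoothing_params(frac = 0.1))$fitted
  inner <- 60:140                          # windows fully inside the region
  expect_lt(max(abs(f[inner + 1] - y[inner + 1])), 1e-8)
})

test_that("adding a constant shifts the fit by the same constant", {
  set.seed(4)
  y <- rnorm(90, 1, 0.1)
  f0 <- loess_periodic(y, smoothing_params(frac = 0.2))$fitted
  f1 <- loess_periodic(y + 3, smoothing_params(frac = 0.2))$fitted
  expect_lt(max(abs(f1 - f0 - 3)), 1e-9)
})

test_that("outlier removal applies the squared-residual threshold", {
  # a residual^2 of 0.04 exceeds the 0.02 cutoff and is removed
  y <- rep(1, 60); y[30] <- 1 + sqrt(0.04) + 1e-9
  s <- remove_outliers_and_refit(y, smoothing_params(frac = 0.3))
  expect_false(s$retained[30])
  expect_equal(sum(!s$retained), 1)
  # refit on the remaining constant is the constant
  expect_lt(max(abs(s$fitted - 1)), 1e-9)
})

test_that("a clean profile passes outlier removal unchanged", {
  set.seed(5)
  y <- 1 + 0.05 * sin(2 * pi * (0:79) / 80)
  s0 <- loess_periodic(y, smoothing_params(frac = 0.2))
  s1 <- remove_outliers_and_refit(y, smoothing_params(frac = 0.2))
  expect_true(all(s1$retained))
  expect_equal(s1$fitted, s0$fitted)
})

test_that("a large spike is removed and the refit recovers the constant", {
  y <- rep(2, 100); y[7] <- 2.5
  s <- remove_outliers_and_refit(y, smoothing_params(frac = 0.25))
  expect_false(s$retained[7])
  expect_lt(max(abs(s$fitted - 2)), 1e-9)
})

test_that("outlier removal is idempotent once residuals are in-bounds", {
  set.seed(6)
  y <- 1 + 0.4 * cos(2 * pi * (0:149) / 150) + rnorm(150, 0, 0.08)
  p1 <- smoothing_params(frac = 0.12, refit_passes = 1)
  p3 <- smoothing_params(frac = 0.12, refit_passes = 3)
  s1 <- remove_outliers_and_refit(y, p1)
  resid2 <- (y - s1$fitted)^2
  if (all(resid2[s1$retained] <= p1$outlier_threshold)) {
    s3 <- remove_outliers_and_refit(y, p3)
    expect_equal(s3$fitted, s1$fitted)
    expect_identical(s3$retained, s1$retained)
  } else succeed("second pass removes more points; idempotence not applicable")
})

test_that("span bookkeeping reports the window the defaults imply", {
  expect_equal(smoothing_window_kbp(4640, frac = 0.10, bin_width = 1000), 460)
  y <- rnorm(4640, 1, 0.01)
  s <- loess_periodic(y, smoothing_params())
  expect_equal(s$q, 464)
  expect_equal(smoothing_window_kbp(s), 460)
})

test_that("degenerate spans are rejected", {
  expect_error(loess_periodic(rnorm(10), smoothing_params(frac = 0.1)),
               "fewer than 3")
  expect_error(loess_periodic(rep(NA_real_, 10) * 1, smoothing_params()),
               "masked")
})
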