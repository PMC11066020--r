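test_that("Poiseuille WSS oracle: 4 mu Q / (pi R^3) within 5 percent", {
  m <- fx_tube()
  f <- fx_steady_field(m, vbar = 6 / (pi * 0.09), R = 0.3)
  wss <- compute_wss(f, m)
  expect_true(all(wss$valid))
  tw <- tawss(wss)
  tau_true <- 4 * 0.04 * 6 / (pi * 0.3^3)
  expect_lt(max(abs(tw$values / tau_true - 1)), 0.05)
})

test_that("the single-probe estimator carries the documented first-order bias", {
  m <- fx_tube()
  f <- fx_steady_field(m, vbar = 6 / (pi * 0.09), R = 0.3)
  tw1 <- tawss(compute_wss(f, m, method = "single"))
  tau_true <- 4 * 0.04 * 6 / (pi * 0.3^3)
  bias <- mean(tw1$values) / tau_true - 1
  # analytic: v(delta)/delta underestimates the gradient by delta/(2R) = 5%
  expect_lt(bias, -0.02)
  expect_gt(bias, -0.10)
})

test_that("zero velocity fields give exactly zero WSS", {
  m <- fx_tube_coarse()
  zero <- velocity_field(0.9 * (0:7) / 8,
                         replicate(8, matrix(0, nrow(m$vertices), 3),
                                   simplify = FALSE), 0.9)
  wss <- compute_wss(zero, m)
  expect_equal(max(abs(unlist(wss$tau))), 0)
})

test_that("shear rate is WSS over viscosity, to machine precision", {
  m <- fx_tube_coarse()
  f <- fx_steady_field(m, vbar = 20, R = 0.25)
  wss <- compute_wss(f, m)
  sr <- shear_rate(wss)
  tw <- tawss(wss)
  expect_equal(sr$values * 0.04, tw$values, tolerance = 1e-12)
  # scalar-field route agrees
  sr2 <- shear_rate(tw)
  expect_equal(sr2$values, sr$values, tolerance = 1e-12)
  # 0.4 dyn/cm2 at 0.04 Poise is the 10 1/s threshold case
  fake <- fx_scalar_field(0.4)
  expect_equal(shear_rate(fake)$values, 10)
})

test_that("TAWSS of a rectified cosine equals 2A/pi", {
  A <- 3.7
  ser <- fx_series_from_fun(function(t) c(A * cos(2 * pi * t), 0, 0),
                            n_frames = 128)
  tw <- tawss(ser)
  expect_equal(tw$values, rep(2 * A / pi, 3), tolerance = 1e-3)
  # constant shear: TAWSS is its magnitude
  serc <- fx_series_from_fun(function(t) c(1, 2, 2), n_frames = 16)
  expect_equal(tawss(serc)$values, rep(3, 3), tolerance = 1e-12)
  # quadrature error shrinks with frame count
  coarse <- fx_series_from_fun(function(t) c(A * cos(2 * pi * t), 0, 0),
                               n_frames = 16)
  expect_lt(max(abs(tw$values - 2 * A / pi)),
            max(abs(tawss(coarse)$values - 2 * A / pi)))
})

test_that("OSI limits: 0 unidirectional, 0.5 full reversal, bounded in between", {
  uni <- fx_series_from_fun(function(t) c(2 + sin(2 * pi * t), 0, 0))
  expect_equal(osi(uni)$values, rep(0, 3), tolerance = 1e-12)
  rev <- fx_series_from_fun(function(t) c(sin(2 * pi * t + pi / 7), 0, 0))
  expect_equal(osi(rev)$values, rep(0.5, 3), tolerance = 1e-6)
  zero <- fx_series_from_fun(function(t) c(0, 0, 0))
  expect_equal(osi(zero)$values, rep(0, 3))
  # property: OSI in [0, 0.5] for random shear schedules
  set.seed(7)
  for (k in 1:20) {
    a <- rnorm(3); b <- rnorm(3); c0 <- rnorm(3)
    ser <- fx_series_from_fun(function(t)
      c0 + a * sin(2 * pi * t) + b * cos(2 * pi * t))
    v <- osi(ser)$values
    expect_true(all(v >= 0 & v <= 0.5))
  }
})

test_that("OSI of the biased sinusoid matches the quadrature oracle", {
  # tau(t) = (1 + 2 cos(2 pi t/T)) e_x: oracle by numerical quadrature
  num <- stats::integrate(function(t) (1 + 2 * cos(2 * pi * t)), 0, 1)$value
  den <- stats::integrate(function(t) abs(1 + 2 * cos(2 * pi * t)), 0, 1,
                          subdivisions = 1000L)$value
  oracle <- 0.5 * (1 - abs(num) / den)
  expect_equal(oracle, 0.152, tolerance = 0.003)  # closed form 0.5(1 - 1/(1/3 + 2 sqrt(3)/pi))
  ser <- fx_series_from_fun(function(t) c(1 + 2 * cos(2 * pi * t), 0, 0),
                            n_frames = 256)
  expect_equal(osi(ser)$values, rep(oracle, 3), tolerance = 0.003)
})

test_that("RRT follows 1/((1 - 2 OSI) TAWSS) with unbounded sentinels", {
  tw <- fx_scalar_field(c(2, 1, 1, 0))
  os <- fx_scalar_field(c(0, 0.25, 0.5, 0.1))
  r <- rrt(tw, os)
  expect_equal(r$values[1:2], c(0.5, 2.0), tolerance = 1e-12)
  expect_true(is.na(r$values[3]))  # OSI = 0.5
  expect_true(is.na(r$values[4]))  # TAWSS = 0
})

test_that("area percentages are strict-threshold and area-weighted", {
  sh <- fx_scalar_field(c(5, 20, 5, 20), areas = c(1, 1, 3, 3))
  roi <- fx_fake_roi(wall_faces = 1:4)
  expect_equal(low_shear_area_pct(sh, roi, 10), 50)
  expect_equal(low_shear_area_pct(fx_scalar_field(rep(5, 4)), roi, 10), 100)
  expect_equal(low_shear_area_pct(fx_scalar_field(rep(20, 4)), roi, 10), 0)
  expect_equal(low_shear_area_pct(fx_scalar_field(rep(10, 4)), roi, 10), 0)  # strict <
  os <- fx_scalar_field(c(0.5, 0.1, 0.5, 0.1), areas = c(1, 1, 1, 1))
  expect_equal(high_osi_area_pct(os, roi, 0.38), 50)
  expect_equal(high_osi_area_pct(fx_scalar_field(rep(0, 4)), roi, 0.38), 0)
  expect_equal(high_osi_area_pct(fx_scalar_field(rep(0.5, 4)), roi, 0.38), 100)
  # monotone in the threshold
  vals <- fx_scalar_field(runif(50, 0, 30))
  roi50 <- fx_fake_roi(1:50)
  pcts <- vapply(c(2, 5, 10, 20), function(th)
    low_shear_area_pct(vals, roi50, th), 0)
  expect_true(all(diff(pcts) >= 0))
})
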