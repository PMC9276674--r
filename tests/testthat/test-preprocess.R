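test_that("adaptive smoothing preserves polynomials and estimates noise", {
  t <- seq(0, 5, length.out = 500)
  quad <- timeseries(tibble::tibble(t = t, x1 = 1 + 2 * t - 0.5 * t^2))
  sm <- smooth_adaptive(quad, polyorder = 3)
  # the filter reproduces polynomials up to its order: smoothed == raw
  expect_equal(ts_states(sm$ts), ts_states(quad), tolerance = 1e-10)
  expect_true(is_smoothed(sm$ts))
  expect_equal(ts_times(sm$ts), t)               # time grid untouched

  noisy <- timeseries(tibble::tibble(
    t = t, x1 = 1 + 2 * t - 0.5 * t^2 + with_seed_rnorm(0, 500, 0.1)))
  smn <- smooth_adaptive(noisy, polyorder = 3)
  expect_lt(abs(smn$report$noise_sd - 0.1) / 0.1, 0.15)

  short <- timeseries(tibble::tibble(t = 1:7, x1 = rnorm(7)))
  expect_mhode_error(smooth_adaptive(short, w0 = 11), "insufficient_data")
})

test_that("central differences are exact on quadratics and drop endpoints", {
  ts <- timeseries(tibble::tibble(t = c(0.9, 1, 1.1), x1 = c(0.9, 1, 1.1)^2))
  d <- estimate_derivatives_central(ts)
  expect_equal(nrow(d), 1)
  expect_equal(d$t, 1)
  expect_equal(d$x1, 2)

  tc <- timeseries(tibble::tibble(t = c(0.9, 1, 1.1), x1 = c(0.9, 1, 1.1)^3))
  expect_equal(estimate_derivatives_central(tc)$x1, (1.331 - 0.729) / 0.2)

  const <- timeseries(tibble::tibble(t = 1:10, x1 = rep(3, 10)))
  expect_equal(estimate_derivatives_central(const)$x1, rep(0, 8))

  two <- timeseries(tibble::tibble(t = 1:2, x1 = 1:2))
  expect_mhode_error(estimate_derivatives_central(two), "insufficient_data")
})

test_that("stationarity enforcement distinguishes noise from a random walk", {
  noise <- with_seed_rnorm(0, 200)
  st <- enforce_stationarity(noise)
  expect_equal(st$d, 0L)

  walk <- cumsum(noise)
  stw <- enforce_stationarity(walk)
  expect_equal(stw$d, 1L)
  expect_equal(stw$series, diff(walk))

  stc <- enforce_stationarity(rep(2, 50))
  expect_equal(stc$d, 0L)
  expect_true(stc$zero_variance)

  expect_mhode_error(enforce_stationarity(rnorm(10)), "insufficient_data")
})

test_that("Granger screening keeps causal terms and the constant", {
  # data from xdot = -x: theta = x Granger-causes x
  t <- seq(0, 6, by = 0.02)
  ts <- timeseries(tibble::tibble(
    t = t,
    x1 = 2 * exp(-t) + with_seed_rnorm(0, length(t), 0.002)), smoothed = TRUE)
  lib <- build_polynomial_terms(n_x = 1, max_degree = 1)
  scr <- suppressWarnings(granger_screen(lib, ts, maxlag = 1, alpha = 0.05))
  expect_true(scr$mask["x1", 1])        # causal term retained
  expect_true(scr$mask["1", 1])         # constant exempt (zero variance)

  # an independent white-noise candidate against white noise is eliminated
  ts2 <- timeseries(tibble::tibble(
    t = seq_len(300), x1 = with_seed_rnorm(0, 300), x2 = with_seed_rnorm(7, 300)),
    smoothed = TRUE)
  lib2 <- basis_library(c("x1", "x2"))
  lib2 <- add_custom_term(lib2, "sin(x2)", "sin(x2)")
  scr2 <- suppressWarnings(granger_screen(lib2, ts2, maxlag = 1, alpha = 0.05))
  expect_false(scr2$mask["sin(x2)", 1])
})

test_that("OLS initialization recovers exact coefficients and flags degeneracy", {
  # exact data from xdot = 2x with library {x, x^2}
  t <- seq(0.0, 1, length.out = 400)
  x <- exp(2 * t)
  ts <- timeseries(tibble::tibble(t = t, x1 = x), smoothed = TRUE)
  lib <- basis_library("x1")
  lib <- add_custom_term(lib, "x1", "x1", protected = TRUE)
  lib <- add_custom_term(lib, "x1sq", "x1^2")
  # independent oracle: direct normal equations on exact derivatives
  Theta <- cbind(x, x^2)[2:399, ]
  d_oracle <- (x[3:400] - x[1:398]) / (t[3:400] - t[1:398])
  beta_oracle <- solve(crossprod(Theta), crossprod(Theta, d_oracle))
  scr <- ols_initialize(lib, ts)
  expect_equal(unname(scr$xi_ols[, 1]), as.numeric(beta_oracle), tolerance = 1e-6)
  expect_equal(unname(scr$xi_ols["x1", 1]), 2, tolerance = 1e-3)
  expect_lt(abs(scr$xi_ols["x1sq", 1]), 1e-3)
  # bounds bracket the estimates and include zero by default
  expect_true(all(scr$lower <= scr$xi_ols & scr$xi_ols <= scr$upper))
  expect_true(all(scr$lower <= 0 & scr$upper >= 0))

  # all-zero derivatives give zero estimates with symmetric bounds
  tsc <- timeseries(tibble::tibble(t = t, x1 = rep(2, 400)), smoothed = TRUE)
  libc <- basis_library("x1")
  libc <- add_custom_term(libc, "x1", "x1")
  scr0 <- ols_initialize(libc, tsc)
  expect_equal(unname(scr0$xi_ols["x1", 1]), 0, tolerance = 1e-12)
  expect_equal(scr0$lower[1, 1], -scr0$upper[1, 1], tolerance = 1e-9)

  # duplicated column triggers the rank-deficiency path
  libd <- basis_library("x1")
  libd <- add_custom_term(libd, "a", "x1")
  libd <- add_custom_term(libd, "b", "x1*1")
  expect_warning(scr_d <- ols_initialize(libd, ts), class = "mhode_warning_rank_deficiency")
  expect_true(any(scr_d$rank_deficient))
})
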