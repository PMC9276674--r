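test_that("coefficient of variation follows the dispersion conventions", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  expect_equal(coefficient_of_variation(c(1, -1)), Inf)    # zero-mean sentinel
  expect_equal(coefficient_of_variation(c(0, 0, 0)), Inf)  # consistently zero
  expect_mhode_error(coefficient_of_variation(3), "argument")

  # scale invariance: thresholding is independent of coefficient units
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(6, mean = runif(1, -3, 3))
    a <- runif(1, 1e-3, 1e3)
    expect_equal(coefficient_of_variation(a * x), coefficient_of_variation(x),
                 tolerance = 1e-12)
  }
})

test_that("convergence rule requires Omega+1 equal trailing sizes", {
  expect_true(check_convergence(c(10, 8, 6, 6, 6, 6), 3))
  expect_false(check_convergence(c(10, 8, 6, 6), 3))
  expect_false(check_convergence(c(4), 1))
  expect_true(check_convergence(c(4, 4), 1))
})

test_that("thresholding prunes high-CV pairs but honours protection", {
  lib <- build_polynomial_terms(n_x = 1, max_degree = 2)  # 1, x1, x1^2
  cfg <- mho_config(psi = 1, grace = 2)
  mk <- function(...) {
    vals <- list(...)
    lapply(seq_along(vals[[1]]), function(w) {
      matrix(vapply(vals, `[[`, numeric(1), w), ncol = 1)
    })
  }
  # stable, stable, wildly varying
  est <- mk(c(1.00, 1.01, 0.99), c(5, 5.1, 4.9), c(0.1, -0.2, 0.3))
  th <- threshold_step(est, lib, cfg, step_index = 3)
  expect_equal(th$cv_table$cv[1], coefficient_of_variation(c(1, 1.01, 0.99)))
  expect_equal(th$drops, tibble::tibble(fn = 3L, state = 1L))

  # same CVs but inside the grace period: the constant is protected...
  est2 <- mk(c(0.1, -0.2, 0.3), c(5, 5.1, 4.9), c(1, 1.01, 0.99))
  th2 <- threshold_step(est2, lib, cfg, step_index = 1)
  expect_equal(nrow(th2$drops), 0)
  # ...but not after the grace period ends
  th3 <- threshold_step(est2, lib, cfg, step_index = 3)
  expect_equal(th3$drops$fn, 1L)

  # numerical-zero floor: tiny stable contribution is pruned regardless of CV
  est4 <- mk(c(1, 1.001, 0.999), c(1e-6, 1.1e-6, 0.9e-6), c(2, 2.01, 1.99))
  th4 <- threshold_step(est4, lib, mho_config(psi = 1, tol_zero = 0.005),
                        step_index = 3, col_rms = c(1, 1, 1), rhs_rms = 1)
  expect_true(2L %in% th4$drops$fn)
  expect_false(1L %in% th4$drops$fn)
})

test_that("aggregation rules: mean/median point estimates and intervals", {
  lib <- build_polynomial_terms(n_x = 1, max_degree = 1)
  lib <- prune(lib, data.frame(fn = 1, state = 1))   # only x1 survives
  cfg <- mho_config(aggregate = "mean")
  est <- lapply(c(1, 3), function(v) matrix(c(0, v), 2, 1))
  m <- mhode:::aggregate_model_internal(est, list(numeric(0), numeric(0)),
                                        1:2, lib, cfg, TRUE)
  expect_equal(m$coefficients$estimate, 2)
  expect_equal(m$Xi["1", 1], 0)          # pruned pair stays an exact zero

  cfg_med <- mho_config(aggregate = "median")
  est3 <- lapply(c(1, 2, 100), function(v) matrix(c(0, v), 2, 1))
  m2 <- mhode:::aggregate_model_internal(est3, rep(list(numeric(0)), 3),
                                         1:3, lib, cfg_med, TRUE)
  expect_equal(m2$coefficients$estimate, 2)

  # identical estimates collapse the interval onto the point
  est_id <- rep(list(matrix(c(0, 7), 2, 1)), 3)
  m3 <- mhode:::aggregate_model_internal(est_id, rep(list(numeric(0)), 3),
                                         1:3, lib, cfg, TRUE)
  expect_equal(m3$coefficients$conf.low, 7)
  expect_equal(m3$coefficients$conf.high, 7)
  expect_true(all(m3$coefficients$conf.low <= m3$coefficients$estimate &
                  m3$coefficients$estimate <= m3$coefficients$conf.high))
})

test_that("simulate_model integrates the aggregated equations", {
  lib <- build_polynomial_terms(n_x = 1, max_degree = 1)
  lib <- prune(lib, data.frame(fn = 1, state = 1))
  cfg <- mho_config()
  # xdot = -x
  est <- rep(list(matrix(c(0, -1), 2, 1)), 2)
  m <- mhode:::aggregate_model_internal(est, rep(list(numeric(0)), 2),
                                        1:2, lib, cfg, TRUE)
  tr <- simulate_model(m, x0 = 1, t_grid = seq(0, 1, by = 0.1))
  expect_equal(tr$x1[11], exp(-1), tolerance = 1e-6)

  # xdot = 0 keeps the state constant
  est0 <- rep(list(matrix(c(0, 0), 2, 1)), 2)
  lib0 <- prune(lib, data.frame(fn = 2, state = 1))
  m0 <- mhode:::aggregate_model_internal(est0, rep(list(numeric(0)), 2),
                                         1:2, lib0, cfg, TRUE)
  tr0 <- simulate_model(m0, x0 = 3.5, t_grid = seq(0, 2, by = 0.5))
  expect_equal(tr0$x1, rep(3.5, 5))
})

test_that("trajectory MSE is a plain mean of squared differences", {
  a <- timeseries(tibble::tibble(t = 1:4, x1 = c(1, 2, 3, 4), x2 = c(0, 0, 0, 0)))
  expect_equal(trajectory_mse(a, a), 0)
  b <- timeseries(tibble::tibble(t = 1:4, x1 = c(2, 3, 4, 5), x2 = c(1, 1, 1, 1)))
  expect_equal(trajectory_mse(a, b), 1)
  cmat <- ts_states(a); cmat[1:4, 1] <- cmat[1:4, 1] + 2   # offset 2 on half the entries
  expect_equal(trajectory_mse(a, cmat), 2)
  short <- timeseries(tibble::tibble(t = 1:3, x1 = 1:3, x2 = 1:3))
  expect_mhode_error(trajectory_mse(a, short), "argument")
})

test_that("window count follows floor((T-H)/s)+1 and short spans error", {
  clean <- lv_segment()
  lib <- basis_library(c("x1", "x2"))
  lib <- add_custom_term(lib, "x1", "x1")
  for (case in list(c(100, 20, 10, 9), c(36, 12, 3, 9), c(10, 4, 2, 4))) {
    T_ <- case[1]; H <- case[2]; s <- case[3]
    tv <- seq(0, T_, by = 0.5)
    expect_length(seq(0, T_ - H + 1e-9, by = s), case[4])
  }
  short <- slice_window(clean, 0, 5)
  expect_mhode_error(
    run_mho(short, lib, mho_config(H = 20, s = 5)), "data")
})

test_that("moving-horizon discovery recovers decay dynamics end to end", {
  # small, fast fixture: xdot = -0.8 x with a 3-term library
  t <- seq(0, 8, by = 0.02)
  ts <- timeseries(tibble::tibble(t = t, x1 = 5 * exp(-0.8 * t)), smoothed = TRUE)
  lib <- build_polynomial_terms(n_x = 1, max_degree = 2)
  fit <- suppressWarnings(
    run_mho(ts, lib, mho_config(H = 3, s = 3 / 8, seed = 7, N = 20)))
  expect_s3_class(fit$model, "mhode_model")
  expect_equal(unname(fit$model$Xi["x1", 1]), -0.8, tolerance = 1e-2)
  # active-set monotonicity across the recorded history
  n_act <- tidy(fit$history)$n_active
  expect_true(all(diff(n_act) <= 0))
  # spurious terms pruned
  expect_equal(model_complexity(fit$model), 1)
})
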