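test_that("benchmark systems expose correct fixed points and signals", {
  # CSTR coolant signal at t = 0 (sin 0 = 0)
  cstr <- make_system("cstr")
  expect_equal(unname(cstr$input_fn(0)), 305)
  expect_equal(unname(cstr$input_fn(2.5)), 305 * (1 + 1 / 125))

  # Brusselator fixed point (a, b/a) for a=1, b=3
  br <- make_system("brusselator")
  expect_equal(system_rhs(br, c(1, 3)), c(0, 0))

  # Lorenz origin is an equilibrium
  lo <- make_system("lorenz")
  expect_equal(system_rhs(lo, c(0, 0, 0)), c(0, 0, 0))

  expect_mhode_error(make_system("volterra_lotka"), "argument")

  # overrides merge shallowly
  lv <- make_system("lotka_volterra", list(params = list(alpha = 2), dt = 0.1))
  expect_equal(lv$params$alpha, 2)
  expect_equal(lv$params$beta, 0.1)
  expect_equal(lv$dt, 0.1)
})

test_that("true-system simulation matches conserved/known behaviour", {
  # van der Pol with mu = 0 is a harmonic oscillator: x^2 + y^2 conserved
  vdp <- make_system("van_der_pol", list(params = list(mu = 0), x0 = c(1, 0),
                                         tspan = c(0, 10)))
  tr <- simulate_true(vdp)
  r2 <- ts_states(tr)[, 1]^2 + ts_states(tr)[, 2]^2
  expect_lt(max(abs(r2 - 1)), 1e-6)

  # Lorenz from the origin stays at the origin
  lo <- make_system("lorenz", list(x0 = c(0, 0, 0), tspan = c(0, 1)))
  expect_equal(max(abs(ts_states(simulate_true(lo)))), 0)

  # Lotka-Volterra stays positive from positive initial conditions
  lv <- make_system("lotka_volterra")
  expect_true(all(ts_states(simulate_true(lv)) > 0))
})

test_that("noise injection is seeded, sized, and leaves inputs clean", {
  lv <- make_system("lotka_volterra", list(tspan = c(0, 20)))
  clean <- simulate_true(lv)
  expect_equal(ts_states(add_noise(clean, 0, seed = 3)), ts_states(clean))
  n1 <- add_noise(clean, 0.5, seed = 9)
  n2 <- add_noise(clean, 0.5, seed = 9)
  expect_identical(ts_states(n1), ts_states(n2))
  expect_mhode_error(add_noise(clean, -1), "argument")

  # law-of-large-numbers check on the empirical noise sd
  big <- timeseries(tibble::tibble(t = seq_len(1e4), x1 = 0))
  noisy <- add_noise(big, 0.5, seed = 4)
  expect_lt(abs(stats::sd(noisy$x1) - 0.5) / 0.5, 0.03)
})

test_that("coefficient error metric follows the structural-miss convention", {
  truth <- matrix(c(1, 2, 0, 0), 2, 2)
  expect_equal(coefficient_error(truth, truth)$error_pct, 0)
  est <- matrix(c(1.1, 2.2, 0, 0), 2, 2)
  expect_equal(coefficient_error(truth, est)$error_pct, 10)
  miss <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(coefficient_error(truth, miss)$error_pct, 50)
  # spurious extras are a separate count, not folded into the percentage
  spur <- matrix(c(1, 2, 3, 0), 2, 2)
  ce <- coefficient_error(truth, spur)
  expect_equal(ce$error_pct, 0)
  expect_equal(ce$n_spurious, 1)
  # invariance to inactive-entry values
  expect_equal(coefficient_error(truth, est)$error_pct,
               coefficient_error(truth, est + matrix(c(0, 0, 9, 9), 2, 2))$error_pct)
  expect_mhode_error(coefficient_error(truth, matrix(0, 3, 2)), "argument")
})

test_that("model complexity counts exact nonzeros", {
  lv <- make_system("lotka_volterra")
  lib <- default_library(lv)
  truth <- mhode:::true_xi_matrix(lv, lib)
  expect_equal(model_complexity(truth), 4)   # alpha x, -beta xy; delta xy, -gamma y
  expect_equal(model_complexity(matrix(0, 3, 2)), 0)
  truth2 <- truth; truth2[which(truth2 != 0)[1]] <- 0
  expect_equal(model_complexity(truth) - model_complexity(truth2), 1)
})

test_that("benchmark reports are reproducible under a fixed master seed", {
  # tiny decay-system benchmark through the public runner, twice
  run <- function() {
    run_benchmark("lotka_volterra", noise = 0.01, replicates = 1,
                  cfg = mho_config(seed = 5, H = 11, s = 11 / 4, omega = 2,
                                   Omega = 2, samples_per_element = 25),
                  noise_kind = "range_fraction",
                  overrides = list(tspan = c(0, 25)))
  }
  b1 <- suppressWarnings(run())
  b2 <- suppressWarnings(run())
  expect_identical(b1$summary, b2$summary)
  expect_identical(b1$replicates$error_pct, b2$replicates$error_pct)
  expect_false(any(b1$replicates$failed))
})
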