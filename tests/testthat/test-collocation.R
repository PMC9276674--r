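test_that("Radau abscissas match closed forms and include the right endpoint", {
  expect_equal(radau_points(1), 1)
  expect_equal(radau_points(2), c(1 / 3, 1), tolerance = 1e-13)
  expect_equal(radau_points(3),
               c((4 - sqrt(6)) / 10, (4 + sqrt(6)) / 10, 1), tolerance = 1e-13)
  for (K in 1:10) {
    tau <- radau_points(K)
    expect_length(tau, K)
    expect_equal(tau[K], 1)
    expect_true(all(diff(tau) > 0) && all(tau > 0))
  }
  expect_mhode_error(radau_points(0), "argument")
  expect_mhode_error(radau_points(11), "argument")
})

test_that("Lagrange derivative table has the interpolation-theory structure", {
  # closed form for two nodes {0, 1}: l0 = 1 - tau, l1 = tau
  tab2 <- lagrange_derivative_table(c(0, 1))
  expect_equal(tab2$D, matrix(c(-1, -1, 1, 1), 2))
  expect_equal(tab2$lend, c(0, 1))

  for (K in 1:6) {
    taus <- c(0, radau_points(K))
    tab <- lagrange_derivative_table(taus)
    expect_lt(max(abs(rowSums(tab$D))), 1e-12)   # partition of unity
    expect_equal(sum(tab$lend), 1, tolerance = 1e-12)
    # delta property via direct polynomial evaluation
    for (k in seq_along(taus)) {
      lk <- vapply(taus, function(t0) {
        prod((t0 - taus[-k]) / (taus[k] - taus[-k]))
      }, numeric(1))
      expect_equal(lk, as.numeric(seq_along(taus) == k), tolerance = 1e-12)
    }
  }
  expect_mhode_error(lagrange_derivative_table(c(0, 0.5, 0.5)), "argument")
})

test_that("grid construction counts nodes and elements correctly", {
  g <- build_grid(0, 1, N = 4, K = 3)
  expect_equal(g$boundaries, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(g$h, rep(0.25, 4))
  expect_length(g$node_times, 4 * 3 + 1)
  expect_mhode_error(build_grid(1, 1, N = 2), "argument")
  expect_mhode_error(build_grid(0, 1, N = 0), "argument")
})

test_that("collocation residuals vanish exactly on collocation solutions", {
  # single element, K = 1 (tau = {0, 1} is implicit Euler): xdot = 1
  g1 <- build_grid(0, 1, N = 1, K = 1)
  X <- array(c(0, 1), dim = c(1, 2, 1))
  F <- array(1, dim = c(1, 1, 1))
  r <- collocation_residuals(g1, X, F)
  expect_equal(as.numeric(r$derivative), 0)

  # equilibrium: constant states, zero rhs
  g <- build_grid(0, 2, N = 3, K = 3)
  Xc <- array(5, dim = c(3, 4, 2))
  Fc <- array(0, dim = c(3, 3, 2))
  rc <- collocation_residuals(g, Xc, Fc)
  expect_equal(max(abs(rc$derivative)), 0)
  expect_equal(max(abs(rc$continuity)), 0)

  # polynomial truth x(t) = t^2 with K >= 2 and exact nodal values
  g2 <- build_grid(0, 1, N = 2, K = 2)
  X2 <- array(g2$times^2, dim = c(2, 3, 1))
  F2 <- array(2 * g2$times[, 2:3], dim = c(2, 2, 1))
  r2 <- collocation_residuals(g2, X2, F2)
  expect_lt(max(abs(r2$derivative)), 1e-12)
  expect_lt(max(abs(r2$continuity)), 1e-12)

  expect_mhode_error(collocation_residuals(g2, X2, array(0, c(2, 3, 1))), "argument")
})

solve_linear_colloc <- function(lambda, h, K) {
  # one Radau step for xdot = lambda * x from x(0) = 1, by direct solve of
  # the collocation equations (independent of the package's DNLP path)
  taus <- c(0, radau_points(K))
  D <- lagrange_derivative_table(taus)$D
  A <- matrix(0, K, K); b <- numeric(K)
  for (j in 1:K) {
    for (k in 1:K) A[j, k] <- D[j + 1, k + 1] / h
    A[j, j] <- A[j, j] - lambda
    b[j] <- -D[j + 1, 1] / h   # x_0 = 1
  }
  xs <- solve(A, b)
  xs[K]  # value at the right endpoint (tau_K = 1)
}

test_that("end-point error scales as O(h^(2K-1)) for xdot = -x", {
  for (K in 2:3) {
    hs <- c(0.2, 0.1, 0.05, 0.025)
    errs <- vapply(hs, function(h) {
      n <- round(1 / h)
      x <- 1
      for (i in seq_len(n)) x <- x * solve_linear_colloc(-1, h, K)
      abs(x - exp(-1))
    }, numeric(1))
    slope <- stats::coef(stats::lm(log(errs) ~ log(hs)))[2]
    expected <- 2 * K - 1
    expect_gt(slope, expected - if (K == 2) 0.3 else 0.5)
    expect_lt(slope, expected + if (K == 2) 0.3 else 0.5)
  }
})

test_that("Radau step is A-stable on a very stiff decay", {
  for (h in c(1e-6, 1e-3, 1, 1e3)) {
    amp <- solve_linear_colloc(-1e6, h, 3)
    expect_lt(abs(amp), 1)
  }
})
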