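# Window-problem assembly and solution on small fixtures. The oracle data
# come from high-accuracy integration of known dynamics (helper lv_segment).

lv_window_fixture <- function(span = 5, N = 60) {
  clean <- lv_segment()
  win <- slice_window(clean, 0, span)
  win <- structure(win, mh_smoothed = TRUE)
  lib <- basis_library(c("x1", "x2"))
  lib <- add_custom_term(lib, "x1", "x1", protected = TRUE)
  lib <- add_custom_term(lib, "x2", "x2", protected = TRUE)
  lib <- add_custom_term(lib, "x1*x2", "x1*x2")
  grid <- build_grid(0, span, N = N, K = 3)
  list(win = win, lib = lib, grid = grid)
}

test_that("assembly counts variables, applies bounds, clips guesses", {
  fx <- lv_window_fixture(span = 2, N = 10)
  p <- assemble_dnlp(fx$win, fx$lib, fx$grid)
  # n_x * N * (K+1) state variables
  expect_equal(p$n_sv, 2 * 10 * 4)
  expect_equal(p$n_pairs, 6)

  lib2 <- prune(fx$lib, data.frame(fn = c(1, 2, 3), state = c(2, 1, 2)))
  p2 <- assemble_dnlp(fx$win, lib2, fx$grid)
  expect_equal(p2$n_pairs, 3)

  bad_bounds <- list(lower = matrix(1, 3, 2), upper = matrix(-1, 3, 2))
  expect_mhode_error(assemble_dnlp(fx$win, fx$lib, fx$grid, bounds = bad_bounds),
                     "argument")

  bounds <- list(lower = matrix(-0.5, 3, 2), upper = matrix(0.5, 3, 2))
  gu <- initialize_guesses(fx$win, fx$grid, fx$lib)
  gu$xi <- rep(2, 6)  # outside bounds
  expect_warning(p3 <- assemble_dnlp(fx$win, fx$lib, fx$grid, bounds = bounds,
                                     guesses = gu),
                 class = "mhode_warning_clip")
  expect_true(all(p3$z0[p3$n_sv + 1:6] <= 0.5))

  g_out <- build_grid(-1, 2, N = 5, K = 3)
  expect_mhode_error(assemble_dnlp(fx$win, fx$lib, g_out), "range")
})

test_that("guess initialization follows the warm-start rules", {
  fx <- lv_window_fixture(span = 2, N = 10)
  scr <- list(xi_ols = matrix(1:6 / 10, 3, 2), lower = NULL, upper = NULL)
  g1 <- initialize_guesses(fx$win, fx$grid, fx$lib, screening = scr)
  pr <- mhode:::active_pairs(fx$lib)
  expect_equal(g1$xi, scr$xi_ols[cbind(pr$fn, pr$state)])

  prev <- list(Xi = matrix(11:16, 3, 2), c = numeric(0))
  g2 <- initialize_guesses(fx$win, fx$grid, fx$lib, screening = scr, prev = prev)
  expect_equal(g2$xi, prev$Xi[cbind(pr$fn, pr$state)])

  # parametric c defaults to the bound midpoint
  libp <- add_custom_term(fx$lib, "arr", "x1*exp(-c1/x2)",
                          params = data.frame(name = "c1", lower = 2, upper = 4, init = 2.5))
  g3 <- initialize_guesses(fx$win, fx$grid, libp)
  expect_equal(unname(g3$c), 3)

  # states are the spline resample of the window at the grid nodes
  rs <- resample(fx$win, fx$grid$node_times)
  expect_equal(unname(g1$states[1, ]), unname(ts_states(rs)[1, ]))
})

test_that("solver recovers exact dynamics from a true-terms library", {
  fx <- lv_window_fixture(span = 5, N = 80)
  gu <- initialize_guesses(fx$win, fx$grid, fx$lib)
  gu$xi <- c(0.5, 0, 0, -1, -0.05, 0.05)  # deliberately rough start
  p <- assemble_dnlp(fx$win, fx$lib, fx$grid, guesses = gu)
  sol <- solve_dnlp(p, list(seed = 1))
  expect_true(sol$status %in% c("optimal", "locally-optimal"))
  expect_lt(sol$objective, 1e-8)
  expect_lt(sol$constraint_violation, 1e-8)
  truth <- matrix(c(1, 0, -0.1, 0, -1.5, 0.075), 3, 2, byrow = FALSE)
  dimnames(truth) <- dimnames(sol$Xi)
  truth["x1", "x1"] <- 1; truth["x2", "x1"] <- 0; truth["x1*x2", "x1"] <- -0.1
  truth["x1", "x2"] <- 0; truth["x2", "x2"] <- -1.5; truth["x1*x2", "x2"] <- 0.075
  act <- truth != 0
  expect_lt(max(abs(sol$Xi[act] - truth[act]) / abs(truth[act])), 1e-4)
})

test_that("solution is invariant to library term order and target perturbation
           touches only the objective", {
  fx <- lv_window_fixture(span = 3, N = 30)
  gu <- initialize_guesses(fx$win, fx$grid, fx$lib)
  p <- assemble_dnlp(fx$win, fx$lib, fx$grid, guesses = gu)
  s1 <- solve_dnlp(p, list(seed = 1))

  libr <- basis_library(c("x1", "x2"))
  libr <- add_custom_term(libr, "x1*x2", "x1*x2")
  libr <- add_custom_term(libr, "x2", "x2", protected = TRUE)
  libr <- add_custom_term(libr, "x1", "x1", protected = TRUE)
  gur <- initialize_guesses(fx$win, fx$grid, libr)
  pr2 <- assemble_dnlp(fx$win, libr, fx$grid, guesses = gur)
  s2 <- solve_dnlp(pr2, list(seed = 1))
  expect_equal(s2$Xi["x1*x2", "x1"], s1$Xi["x1*x2", "x1"], tolerance = 1e-6)
  expect_equal(s2$Xi["x2", "x2"], s1$Xi["x2", "x2"], tolerance = 1e-6)

  # perturbing the data targets never changes the constraint structure
  p_pert <- p
  p_pert$xtil <- p$xtil + 0.01
  r1 <- mhode:::dnlp_resid(p, p$z0)
  r2 <- mhode:::dnlp_resid(p_pert, p$z0)
  expect_equal(length(r1$con), length(r2$con))
  expect_equal(r1$con, r2$con)            # constraints identical
  expect_false(isTRUE(all.equal(r1$mis, r2$mis)))  # objective differs
})

test_that("collocation constraints are satisfied at the reported solution", {
  fx <- lv_window_fixture(span = 3, N = 30)
  p <- assemble_dnlp(fx$win, fx$lib, fx$grid,
                     guesses = initialize_guesses(fx$win, fx$grid, fx$lib))
  sol <- solve_dnlp(p, list(seed = 1))
  # independent re-check through collocation_residuals
  K <- fx$grid$K; N <- fx$grid$N
  X <- array(0, dim = c(N, K + 1, 2))
  for (s in 1:2) X[, , s] <- matrix(sol$states[, s], N, K + 1, byrow = TRUE)
  Fv <- array(0, dim = c(N, K, 2))
  for (i in 1:N) {
    for (j in 1:K) {
      xv <- X[i, j + 1, ]
      th <- c(xv[1], xv[2], xv[1] * xv[2])
      Fv[i, j, ] <- as.numeric(t(sol$Xi) %*% th)
    }
  }
  rr <- collocation_residuals(fx$grid, X, Fv)
  expect_lt(max(abs(rr$derivative)), 1e-6)
  expect_lt(max(abs(rr$continuity)), 1e-7)
})
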