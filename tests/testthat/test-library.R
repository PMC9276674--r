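test_that("monomial enumeration matches the combinatorial count", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 2)
  expect_equal(function_names(lib), c("1", "x1", "x2", "x1^2", "x1*x2", "x2^2"))

  lib0 <- build_polynomial_terms(n_x = 3, max_degree = 0)
  expect_equal(n_functions(lib0), 1)

  # C(n + d, d) for several (n, d), against brute-force enumeration
  for (n in 1:4) {
    for (d in 0:6 - 0) {
      expect_equal(n_functions(build_polynomial_terms(n_x = n, max_degree = d)),
                   choose(n + d, d))
    }
  }
  expect_mhode_error(build_polynomial_terms(2, max_degree = -1), "argument")
})

test_that("protected flags mark the constant and pure-linear terms", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 3)
  prot <- vapply(lib$functions, `[[`, logical(1), "protected")
  expect_equal(function_names(lib)[prot], c("1", "x1", "x2"))
})

test_that("elementary and custom terms validate their symbols and bounds", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 1)
  lib2 <- add_elementary_terms(lib, c("sin", "cos"), c("x1", "x2"))
  expect_equal(n_functions(lib2) - n_functions(lib), 4)
  expect_mhode_error(add_elementary_terms(lib, "sin", "x9"), "argument")
  expect_mhode_error(add_elementary_terms(lib2, "sin", "x1"), "library")

  # Arrhenius-style parametric term
  lib3 <- add_custom_term(lib, "arr", "x1*exp(-c1/x2)",
                          params = data.frame(name = "c1", lower = 1000,
                                              upper = 20000, init = 8000))
  expect_equal(n_functions(lib3), n_functions(lib) + 1)
  expect_mhode_error(
    add_custom_term(lib, "bad", "x1*exp(-c1/x2)",
                    params = data.frame(name = "c1", lower = 10, upper = 5, init = 7)),
    "argument")
  expect_mhode_error(
    add_custom_term(lib, "bad", "x1*exp(-c1/x2)",
                    params = data.frame(name = "c1", lower = 0, upper = 5, init = 7)),
    "argument")
  expect_mhode_error(add_custom_term(lib, "bad", "x1 +* 2"), "expression")
  expect_mhode_error(add_custom_term(lib, "bad", "x7 + x1"), "argument")
})

test_that("dictionary evaluation matches direct arithmetic", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 2)
  M <- evaluate_matrix(lib, matrix(c(2, 3), 1))
  expect_equal(as.vector(M), c(1, 2, 3, 4, 6, 9))

  # constant column of ones; linear terms return the data unchanged
  X <- matrix(rnorm(20), 10)
  M2 <- evaluate_matrix(lib, X)
  expect_equal(M2[, "1"], rep(1, 10))
  expect_equal(M2[, "x1"], X[, 1])
  expect_equal(M2[, "x2"], X[, 2])

  # parametric collapse cases
  lib_u <- basis_library(c("x1"), "u1")
  lib_u <- add_custom_term(lib_u, "uexp", "u1*exp(-c1*x1)",
                           params = data.frame(name = "c1", lower = 0, upper = 5, init = 0))
  v <- evaluate_matrix(lib_u, matrix(1), matrix(2), c_values = list(c1 = 0))
  expect_equal(as.numeric(v), 2)                 # c = 0 collapses the exponential
  v0 <- evaluate_matrix(lib_u, matrix(0), matrix(5), c_values = list(c1 = 3))
  expect_equal(as.numeric(v0), 5)                # exp(-c * 0) = 1
  expect_mhode_error(
    evaluate_matrix(lib_u, matrix(1), matrix(1), c_values = list(c1 = 99)),
    "argument")

  # domain violation is reported with the offending function
  lib_div <- add_custom_term(basis_library("x1"), "inv", "1/x1")
  expect_mhode_error(evaluate_matrix(lib_div, matrix(c(1, 0), 2)), "evaluation")
})

test_that("pruning is monotone, idempotent, and mask-consistent", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 2)
  expect_equal(sum(active_mask(lib)), 12)
  lib2 <- prune(lib, data.frame(fn = 3, state = 1))
  expect_equal(sum(active_mask(lib2)), 11)
  lib3 <- prune(lib2, data.frame(fn = 3, state = 1))   # idempotent
  expect_identical(active_mask(lib3), active_mask(lib2))
  lib4 <- prune(lib3, data.frame(fn = c(3, 4, 5), state = c(2, 1, 2)))
  expect_true(all(which(!active_mask(lib4)) %in%
                  c(which(!active_mask(lib3)), 4, 6 + 3, 6 + 5)))
  expect_mhode_error(prune(lib, data.frame(fn = 99, state = 1)), "argument")
})

test_that("library JSON round-trip preserves terms, params, mask", {
  lib <- build_polynomial_terms(n_x = 2, max_degree = 2)
  lib <- add_custom_term(lib, "arr", "x1*exp(-c1/x2)",
                         params = data.frame(name = "c1", lower = 1, upper = 10, init = 5))
  lib <- prune(lib, data.frame(fn = c(2, 7), state = c(1, 2)))
  path <- withr::local_tempfile(fileext = ".json")
  library_to_json(lib, path)
  back <- library_from_json(path)
  expect_equal(function_names(back), function_names(lib))
  expect_equal(active_mask(back), active_mask(lib))
  expect_equal(mhode:::lib_param_table(back), mhode:::lib_param_table(lib))
  X <- matrix(abs(rnorm(10)) + 0.5, 5)
  expect_equal(evaluate_matrix(back, X), evaluate_matrix(lib, X))
})
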