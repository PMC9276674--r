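# Shared fixtures built in code: small trajectories, libraries, and a
# cached zero-noise Lotka-Volterra segment used by several files.

lv_segment <- local({
  cache <- NULL
  function(span = 10, dt = 0.02) {
    if (is.null(cache)) {
      sys <- make_system("lotka_volterra", list(tspan = c(0, span), dt = dt))
      cache <<- simulate_true(sys)
    }
    cache
  }
})

tiny_ts <- function(n = 9, f = function(t) cbind(x1 = t^2, x2 = 2 * t)) {
  t <- seq(0, 2, length.out = n)
  timeseries(tibble::tibble(t = t, as.data.frame(f(t))), time = "t")
}

expect_mhode_error <- function(expr, class) {
  expect_error(expr, class = paste0("mhode_error_", class))
}

with_seed_rnorm <- function(seed, n, sd = 1) {
  mhode:::with_seed(seed, stats::rnorm(n, 0, sd))
}
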