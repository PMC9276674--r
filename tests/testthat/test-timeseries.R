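test_that("construction validates shape, order and schema", {
  df <- data.frame(t = c(2, 0, 1), x1 = c(4, 0, 1), x2 = c(8, 1, 2))
  ts <- timeseries(df, time = "t")
  expect_equal(ts_times(ts), c(0, 1, 2))        # sorted by time
  expect_equal(n_states(ts), 2)
  expect_equal(n_inputs(ts), 0)

  expect_mhode_error(timeseries(df, time = "time"), "schema")
  expect_mhode_error(timeseries(data.frame(t = c(0, 1, 1), x1 = 1:3)), "validation")
  expect_mhode_error(timeseries(data.frame(t = c(0, 1, NA), x1 = 1:3)), "validation")

  ts2 <- timeseries(data.frame(t = 0:2, x1 = 1:3, u1 = 4:6),
                    states = "x1", inputs = "u1")
  expect_equal(n_inputs(ts2), 1)
  expect_equal(as.vector(ts_inputs(ts2)), c(4, 5, 6))
})

test_that("CSV round-trip reproduces the series exactly", {
  set.seed(7)
  df <- data.frame(t = sort(runif(20)), x1 = rnorm(20), x2 = rnorm(20),
                   u1 = rnorm(20))
  ts <- timeseries(df, states = c("x1", "x2"), inputs = "u1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(ts, path)
  back <- read_timeseries(path, list(time_col = "t",
                                     state_cols = c("x1", "x2"),
                                     input_cols = "u1"))
  expect_identical(ts_states(back), ts_states(ts))
  expect_identical(ts_times(back), ts_times(ts))
  expect_identical(ts_inputs(back), ts_inputs(ts))

  # no input columns emitted when n_u = 0
  ts0 <- timeseries(df[c("t", "x1")])
  write_timeseries(ts0, path)
  expect_named(readr::read_csv(path, show_col_types = FALSE), c("t", "x1"))

  empty <- timeseries(data.frame(t = numeric(), x1 = numeric()))
  expect_mhode_error(write_timeseries(empty, path), "io")
  expect_mhode_error(read_timeseries("no-such-file.csv"), "io")
})

test_that("slice_window uses a closed interval and rejects empty windows", {
  ts <- timeseries(data.frame(t = 0:3, x1 = 10:13))
  w <- slice_window(ts, 1, 2)
  expect_equal(ts_times(w), c(1, 2))
  expect_mhode_error(slice_window(ts, 0.5, 0.9), "window")
  expect_mhode_error(slice_window(ts, 2, 1), "argument")
  full <- slice_window(ts, min(ts_times(ts)), max(ts_times(ts)))
  expect_equal(ts_states(full), ts_states(ts))
})

test_that("resampling is exact on knots, cubics, and linear in the data", {
  t <- 0:5
  ts <- timeseries(data.frame(t = t, x1 = t, x2 = t^3))
  # exact on linear and cubic data (not-a-knot property)
  out <- resample(ts, c(1.5, 2.5))
  expect_equal(out$x1, c(1.5, 2.5), tolerance = 1e-12)
  expect_equal(out$x2, c(1.5^3, 2.5^3), tolerance = 1e-12)
  # knot values reproduced exactly
  at_knots <- resample(ts, t)
  expect_equal(ts_states(at_knots), ts_states(ts), tolerance = 1e-12)
  # linearity in the data
  ts3 <- timeseries(data.frame(t = t, x1 = 3 * sin(t)))
  ts1 <- timeseries(data.frame(t = t, x1 = sin(t)))
  q <- seq(0.3, 4.7, by = 0.5)
  expect_equal(resample(ts3, q)$x1, 3 * resample(ts1, q)$x1, tolerance = 1e-12)

  expect_mhode_error(resample(ts, 7), "extrapolation")
  short <- timeseries(data.frame(t = 0:2, x1 = 0:2))
  expect_mhode_error(resample(short, 1), "insufficient_data")
})
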