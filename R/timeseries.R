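#' Construct a sampled-trajectory table
#'
#' A time series is an ordinary tibble with one time column, one column per
#' state variable, and optionally one column per exogenous input, plus
#' attributes recording which column plays which role. All package verbs
#' (`slice_window()`, `resample()`, `smooth_adaptive()`, `run_mho()`, ...)
#' take and return this shape, so pipelines chain with the pipe.
#'
#' @param data data frame containing the columns named below.
#' @param time name of the time column (strictly increasing, finite).
#' @param states character vector of state column names. Defaults to every
#'   numeric column that is neither the time column nor an input.
#' @param inputs character vector of exogenous-input column names (may be
#'   empty).
#' @param smoothed logical flag distinguishing raw measurements from
#'   pre-processed (denoised) trajectories.
#' @return a `mhode_ts` tibble, rows sorted by time.
#' @examples
#' ts <- timeseries(data.frame(t = 0:3, x1 = c(1, 2, 4, 8)), time = "t")
#' n_states(ts)
#' @export
timeseries <- function(data, time = "t", states = NULL, inputs = character(), smoothed = FALSE) {
  data <- tibble::as_tibble(data)
  if (!time %in% names(data)) {
    stop_mhode(paste0("declared time column '", time, "' not present"), "schema")
  }
  inputs <- inputs %||% character()
  if (is.null(states)) {
    states <- setdiff(names(data), c(time, inputs))
  }
  missing_cols <- setdiff(c(states, inputs), names(data))
  if (length(missing_cols) > 0) {
    stop_mhode(paste0("columns not present: ", paste(missing_cols, collapse = ", ")), "schema")
  }
  for (cn in c(time, states, inputs)) {
    if (!is.numeric(data[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[cn]])))))
      stop_mhode(paste0("non-numeric values in column '", cn, "' (row ",
                        if (length(bad)) bad[1] else "?", ")"), "parse")
    }
  }
  data <- data[c(time, states, inputs)]
  ord <- order(data[[time]])
  data <- data[ord, , drop = FALSE]
  new_timeseries(data, time, states, inputs, smoothed)
}

new_timeseries <- function(data, time, states, inputs, smoothed) {
  tvals <- data[[time]]
  if (anyNA(data) || !all(vapply(data, function(v) all(is.finite(v)), logical(1)))) {
    stop_mhode("time series contains non-finite values", "validation")
  }
  if (length(tvals) > 1 && any(diff(tvals) <= 0)) {
    stop_mhode("times must be strictly increasing (duplicates rejected)", "validation")
  }
  structure(
    data,
    class = c("mhode_ts", class(tibble::tibble())),
    mh_time = time, mh_states = states, mh_inputs = inputs,
    mh_smoothed = isTRUE(smoothed)
  )
}

#' @export
print.mhode_ts <- function(x, ...) {
  cat(sprintf(
    "<mhode_ts> %d samples, %d state(s) [%s], %d input(s)%s%s\n",
    nrow(x), n_states(x), paste(state_names(x), collapse = ", "),
    n_inputs(x),
    if (n_inputs(x)) paste0(" [", paste(input_names(x), collapse = ", "), "]") else "",
    if (is_smoothed(x)) ", smoothed" else ""
  ))
  NextMethod()
}

#' Accessors for `mhode_ts` objects
#'
#' @param ts a [timeseries()] object.
#' @return `ts_times()` the time vector; `ts_states()`/`ts_inputs()` numeric
#'   matrices (m x n_x and m x n_u); the rest scalars/character vectors.
#' @name ts-accessors
NULL

#' @rdname ts-accessors
#' @export
ts_times <- function(ts) ts[[attr(ts, "mh_time")]]

#' @rdname ts-accessors
#' @export
ts_states <- function(ts) {
  as.matrix(ts[attr(ts, "mh_states")])
}

#' @rdname ts-accessors
#' @export
ts_inputs <- function(ts) {
  cols <- attr(ts, "mh_inputs")
  if (length(cols) == 0) {
    matrix(numeric(0), nrow = nrow(ts), ncol = 0)
  } else {
    as.matrix(ts[cols])
  }
}

#' @rdname ts-accessors
#' @export
state_names <- function(ts) attr(ts, "mh_states")

#' @rdname ts-accessors
#' @export
input_names <- function(ts) attr(ts, "mh_inputs")

#' @rdname ts-accessors
#' @export
n_states <- function(ts) length(attr(ts, "mh_states"))

#' @rdname ts-accessors
#' @export
n_inputs <- function(ts) length(attr(ts, "mh_inputs"))

#' @rdname ts-accessors
#' @export
is_smoothed <- function(ts) isTRUE(attr(ts, "mh_smoothed"))

# Rebuild an mhode_ts with the same roles but new state values.
ts_replace_states <- function(ts, states_mat, smoothed = is_smoothed(ts)) {
  out <- tibble::as_tibble(as.data.frame(ts))
  out[attr(ts, "mh_states")] <- as.data.frame(states_mat)
  new_timeseries(out, attr(ts, "mh_time"), attr(ts, "mh_states"),
                 attr(ts, "mh_inputs"), smoothed)
}

#' Read a time series from CSV
#'
#' CSV dialect: UTF-8, comma separator, '.' decimal, mandatory header.
#' Rows are sorted by time; duplicate timestamps are rejected.
#'
#' @param path CSV file path.
#' @param schema list with entries `time_col`, `state_cols`, `input_cols`
#'   (defaults: `t`, all remaining columns, none).
#' @return a [timeseries()] tibble.
#' @export
read_timeseries <- function(path, schema = list()) {
  if (!file.exists(path)) stop_mhode(paste0("file not found: ", path), "io")
  # parse cells as text and convert via strtod for correctly-rounded doubles
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  for (cn in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad) > 0) {
      stop_mhode(paste0("non-numeric value in column '", cn, "' at row ", bad[1]), "parse")
    }
    df[[cn]] <- v
  }
  timeseries(df,
             time = schema$time_col %||% "t",
             states = schema$state_cols,
             inputs = schema$input_cols %||% character())
}

#' Write a time series to CSV
#'
#' The inverse of [read_timeseries()]: values are written with shortest
#' round-trip precision so `read_timeseries(write_timeseries(ts))`
#' reproduces `ts` exactly.
#'
#' @param ts a [timeseries()] object with at least one row.
#' @param path output file path.
#' @return `ts`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (nrow(ts) == 0) stop_mhode("refusing to write an empty time series", "io")
  df <- tibble::as_tibble(as.data.frame(ts))
  # %.17g guarantees binary round-trip of doubles through the CSV
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  readr::write_csv(df, path, progress = FALSE)
  invisible(ts)
}

#' Extract a closed time window
#'
#' Returns all samples with `t_start <= t <= t_end` (closed-interval
#' convention, matching the inclusive collocation element boundaries).
#'
#' @param ts a [timeseries()] object.
#' @param t_start,t_end window bounds, `t_start < t_end`.
#' @return a [timeseries()] tibble restricted to the window.
#' @export
slice_window <- function(ts, t_start, t_end) {
  if (!(t_start < t_end)) stop_mhode("t_start must be < t_end", "argument")
  tv <- ts_times(ts)
  keep <- tv >= t_start & tv <= t_end
  if (!any(keep)) stop_mhode("window contains no samples", "window")
  out <- ts[keep, , drop = FALSE]
  new_timeseries(tibble::as_tibble(as.data.frame(out)), attr(ts, "mh_time"),
                 attr(ts, "mh_states"), attr(ts, "mh_inputs"), is_smoothed(ts))
}

#' Resample a trajectory onto arbitrary time points
#'
#' Interpolates every state (and input) column with a not-a-knot cubic
#' spline ([spline_notaknot()]). Values at original sample times are
#' reproduced exactly, and data sampled from any polynomial of degree <= 3
#' are interpolated exactly. Extrapolation is refused.
#'
#' @param ts a [timeseries()] object with at least 4 samples.
#' @param query_times increasing time points within the sampled range.
#' @return a [timeseries()] tibble at `query_times`.
#' @export
resample <- function(ts, query_times) {
  if (nrow(ts) < 4) stop_mhode("resampling needs at least 4 samples", "insufficient_data")
  tv <- ts_times(ts)
  cols <- c(attr(ts, "mh_states"), attr(ts, "mh_inputs"))
  out <- tibble::tibble(.rows = length(query_times))
  out[[attr(ts, "mh_time")]] <- query_times
  for (cn in cols) {
    out[[cn]] <- spline_notaknot(tv, ts[[cn]], query_times)
  }
  new_timeseries(out, attr(ts, "mh_time"), attr(ts, "mh_states"),
                 attr(ts, "mh_inputs"), is_smoothed(ts))
}
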