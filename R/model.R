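#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.mhode_model <- function(x, ...) {
  cat("<mhode_model> discovered governing equations",
      if (x$converged) "(converged)" else "(data exhausted before convergence)", "\n")
  for (eq in x$equations) cat("  ", eq, "\n")
  cat(sprintf("  aggregated over %d window(s) by %s\n",
              length(x$provenance), x$aggregate))
  invisible(x)
}

#' Tidy a discovered model
#'
#' One row per surviving coefficient: term, state equation, point estimate
#' and empirical 2.5/97.5 percentile interval over post-convergence windows.
#'
#' @param x a `mhode_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.mhode_model <- function(x, ...) {
  out <- x$coefficients
  if (nrow(x$c_params) > 0) {
    out <- dplyr::bind_rows(out,
      tibble::tibble(term = paste0("<param> ", x$c_params$param), state = NA_character_,
                     estimate = x$c_params$estimate, conf.low = x$c_params$conf.low,
                     conf.high = x$c_params$conf.high,
                     n_windows = length(x$provenance)))
  }
  out
}

#' One-row model summary
#'
#' @param x a `mhode_model`.
#' @param ... unused.
#' @return tibble with term count (complexity), number of states, windows
#'   aggregated, and convergence flag.
#' @export
glance.mhode_model <- function(x, ...) {
  tibble::tibble(
    n_terms = sum(x$Xi != 0),
    n_states = ncol(x$Xi),
    n_params = length(x$c),
    n_windows = length(x$provenance),
    converged = x$converged
  )
}

#' @export
print.mhode_history <- function(x, ...) {
  cat(sprintf("<mhode_history> %d window(s), H=%.4g, s=%.4g, %d thresholding step(s)%s\n",
              nrow(x$windows), x$H, x$s, length(x$sizes),
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Tidy the window history
#'
#' @param x a `mhode_history`.
#' @param ... unused.
#' @return tibble with one row per window (estimates as list-columns
#'   dropped): window, times, status, objective, active count.
#' @export
tidy.mhode_history <- function(x, ...) {
  dplyr::select(x$windows, -dplyr::any_of(c("Xi", "c")))
}

#' Serialize a discovered model to JSON
#'
#' Per state: the symbolic right-hand side, the coefficient table (term,
#' value, interval), nonlinear parameters, and provenance (post-convergence
#' window indices).
#'
#' @param model a `mhode_model`.
#' @param path file path.
#' @export
model_to_json <- function(model, path) {
  doc <- list(
    equations = stats::setNames(as.list(model$equations), model$library$state_names),
    coefficients = model$coefficients,
    parameters = model$c_params,
    provenance = model$provenance,
    converged = model$converged,
    aggregate = model$aggregate
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
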