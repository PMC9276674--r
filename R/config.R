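# Default run configuration tree; unknown keys are rejected by parse_config
# so config typos fail loudly.
config_defaults <- function() {
  list(
    data = NULL,
    schema = list(time_col = "t", state_cols = NULL, input_cols = NULL),
    library = list(path = NULL, max_degree = 5, trig = TRUE),
    smoothing = list(polyorder = 3, tol = 0.01, w0 = 5, dw = 2),
    screening = list(enabled = TRUE, alpha = 0.05, maxlag = 1,
                     conf = 0.999, s_widen = 5),
    mho = list(H = NULL, s = NULL, omega = 3, psi = 1, Omega = 5, grace = 2,
               aggregate = "mean", K = 3, N = NULL, samples_per_element = 12),
    solver = list(feas_tol = 1e-8, opt_tol = 1e-8, max_iter = 80,
                  max_outer = 12, rho0 = 1e8),
    out_dir = ".",
    seed = 1
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_mhode(paste0("unknown configuration key '", full, "'"), "config")
    }
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv)) && length(dv) > 0 && is.list(uv)) {
      defaults[[key]] <- merge_config(dv, uv, c(path, key))
    } else {
      # single-bracket assignment so an explicit NULL overwrites the
      # default instead of deleting the key
      defaults[key] <- list(uv)
    }
  }
  defaults
}

#' Parse a run configuration file
#'
#' Reads YAML or JSON, fills defaults for absent keys, and rejects unknown
#' keys (typo safety).
#'
#' @param path configuration file (`.yaml`/`.yml`/`.json`).
#' @return fully-resolved configuration list of class `mhode_runconfig`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop_mhode(paste0("config not found: ", path), "config")
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(config_defaults(), user %||% list())
  structure(cfg, class = "mhode_runconfig")
}

#' Emit a configuration back to YAML
#' @param cfg a `mhode_runconfig` (or plain list).
#' @param path output path.
#' @export
emit_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_to_mho <- function(cfg) {
  m <- cfg$mho
  mho_config(H = m$H, s = m$s, omega = m$omega, psi = m$psi, Omega = m$Omega,
             grace = m$grace, aggregate = m$aggregate, K = m$K, N = m$N,
             samples_per_element = m$samples_per_element, seed = cfg$seed,
             solver = cfg$solver)
}

# minimal flag parser: --key value and bare switches
parse_argv <- function(argv, switches = character()) {
  out <- list(positional = character())
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (key %in% switches) {
        out[[key]] <- TRUE
        i <- i + 1
      } else {
        if (i == length(argv)) stop_mhode(paste0("flag --", key, " needs a value"), "cli")
        out[[key]] <- argv[i + 1]
        i <- i + 2
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1
    }
  }
  out
}

run_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%OS2"), " ", sprintf(...))
  cat(msg, "\n")
  if (!is.null(con)) writeLines(msg, con)
}

#' Discover governing equations from the command line
#'
#' Thin driver over the package pipeline: read data, build or load the
#' dictionary, preprocess, run the moving-horizon discovery, and write
#' `model.json`, `history.csv` and `run.log` to the output directory.
#'
#' @param argv character vector of CLI arguments. Flags: `--data`,
#'   `--config`, `--horizon`, `--step`, `--psi`, `--omega`, `--patience`,
#'   `--elements`, `--colloc-points`, `--seed`, `--out`, `--dry-run`.
#' @return integer exit status (0 on success), invisibly.
#' @export
cmd_discover <- function(argv = character()) {
  status <- tryCatch({
    args <- parse_argv(argv, switches = "dry-run")
    cfg <- if (!is.null(args$config)) parse_config(args$config) else
      structure(config_defaults(), class = "mhode_runconfig")
    if (!is.null(args$data)) cfg$data <- args$data
    if (!is.null(args$seed)) cfg$seed <- as.integer(args$seed)
    for (map in list(c("horizon", "H"), c("step", "s"), c("psi", "psi"),
                     c("omega", "omega"), c("patience", "Omega"),
                     c("elements", "N"), c("colloc-points", "K"))) {
      if (!is.null(args[[map[1]]])) cfg$mho[[map[2]]] <- as.numeric(args[[map[1]]])
    }
    if (!is.null(args$out)) cfg$out_dir <- args$out
    if (is.null(cfg$data)) stop_mhode("no data file given (--data or config)", "cli")
    if (!file.exists(cfg$data)) stop_mhode(paste0("data file not found: ", cfg$data), "cli")

    ts <- read_timeseries(cfg$data, cfg$schema)
    lib <- if (!is.null(cfg$library$path)) {
      library_from_json(cfg$library$path)
    } else {
      l <- build_polynomial_terms(n_states(ts), max_degree = cfg$library$max_degree,
                                  state_names = state_names(ts),
                                  input_names = input_names(ts))
      if (isTRUE(cfg$library$trig)) l <- add_elementary_terms(l, c("sin", "cos")) else l
    }
    if (isTRUE(args[["dry-run"]])) {
      cat("dry run: data", cfg$data, "with", nrow(ts), "samples,",
          n_functions(lib), "basis functions; seed", cfg$seed, "\n")
      return(invisible(0L))
    }
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logcon <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
    on.exit(close(logcon), add = TRUE)
    run_log(logcon, "discover: m=%d n_x=%d n_theta=%d seed=%d",
            nrow(ts), n_states(ts), n_functions(lib), cfg$seed)
    pp <- preprocess(ts, lib,
                     use_granger = isTRUE(cfg$screening$enabled),
                     alpha = cfg$screening$alpha, maxlag = cfg$screening$maxlag,
                     conf = cfg$screening$conf, s_widen = cfg$screening$s_widen,
                     polyorder = cfg$smoothing$polyorder, tol = cfg$smoothing$tol,
                     w0 = cfg$smoothing$w0, dw = cfg$smoothing$dw)
    run_log(logcon, "screening retained %d/%d pairs", sum(pp$lib$active), length(pp$lib$active))
    fit <- run_mho(pp$ts, pp$lib, config_to_mho(cfg), screening = pp$screening,
                   ts_raw = ts)
    hist_tab <- tidy.mhode_history(fit$history)
    for (k in seq_len(nrow(hist_tab))) {
      run_log(logcon, "window %d: objective=%.4e active=%d status=%s",
              hist_tab$window[k], hist_tab$objective[k], hist_tab$n_active[k],
              hist_tab$status[k])
    }
    model_to_json(fit$model, file.path(cfg$out_dir, "model.json"))
    readr::write_csv(hist_tab, file.path(cfg$out_dir, "history.csv"), progress = FALSE)
    run_log(logcon, "done: %d terms", model_complexity(fit$model))
    0L
  }, mhode_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Benchmark a canonical system from the command line
#'
#' Flags: `--system`, `--noise` (comma-separated levels), `--replicates`,
#' `--seed`, `--out`.
#'
#' @param argv character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
cmd_benchmark <- function(argv = character()) {
  status <- tryCatch({
    args <- parse_argv(argv)
    name <- args$system %||% "lotka_volterra"
    noise <- as.numeric(strsplit(args$noise %||% "0", ",")[[1]])
    reps <- as.integer(args$replicates %||% "1")
    seed <- as.integer(args$seed %||% "1")
    out_dir <- args$out %||% "."
    bench <- run_benchmark(name, noise = noise, replicates = reps,
                           cfg = mho_config(seed = seed))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(bench$summary, file.path(out_dir, "benchmark_summary.csv"), progress = FALSE)
    readr::write_csv(dplyr::select(bench$replicates, -dplyr::any_of(c("trace", "sigma"))),
                     file.path(out_dir, "benchmark_replicates.csv"), progress = FALSE)
    print(bench$summary)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Simulate a benchmark system from the command line
#'
#' Writes a clean (optionally noise-contaminated) trajectory CSV for one of
#' the built-in systems. Flags: `--system`, `--noise` (absolute sd),
#' `--seed`, `--out` (file path, default `trajectory.csv`).
#'
#' @param argv character vector of CLI arguments.
#' @return integer exit status, invisibly.
#' @export
cmd_simulate <- function(argv = character()) {
  status <- tryCatch({
    args <- parse_argv(argv)
    sys <- make_system(args$system %||% "lotka_volterra")
    ts <- simulate_true(sys)
    noise <- as.numeric(args$noise %||% "0")
    if (noise > 0) ts <- add_noise(ts, noise, seed = as.integer(args$seed %||% "1"))
    out <- args$out %||% "trajectory.csv"
    write_timeseries(ts, out)
    message("wrote ", out, " (", nrow(ts), " samples)")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' CLI dispatcher
#'
#' Subcommands: `discover`, `simulate`, `benchmark`.
#'
#' @param argv full argument vector, first element the subcommand.
#' @return integer exit status, invisibly.
#' @export
cmd_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message("usage: mhode <discover|simulate|benchmark> [flags]")
    return(invisible(2L))
  }
  switch(argv[1],
         discover = cmd_discover(argv[-1]),
         simulate = cmd_simulate(argv[-1]),
         benchmark = cmd_benchmark(argv[-1]),
         {
           message("unknown subcommand: ", argv[1])
           invisible(2L)
         })
}
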