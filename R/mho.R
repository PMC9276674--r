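#' Moving-horizon discovery configuration
#'
#' @param H horizon length (time units of the data). `NULL` = automatic:
#'   twice the fundamental oscillation period estimated from the leading
#'   state's spectrum when that fits comfortably in the record (one period
#'   on short records), else a tenth of the span.
#' @param s window step (time units); default `H / 8` so consecutive windows
#'   overlap strongly and many coefficient estimates accumulate between
#'   thresholding steps.
#' @param omega thresholding period: prune every `omega` successful windows.
#' @param psi variability tolerance: a (function, state) pair is pruned when
#'   the coefficient of variation of its estimates since the last
#'   thresholding step exceeds `psi` (strictly). The default 1 separates
#'   "spread comparable to the mean" from stable estimates independently of
#'   coefficient units.
#' @param Omega convergence patience: stop once the active-set size is
#'   unchanged over `Omega` consecutive thresholding steps.
#' @param grace number of initial thresholding steps during which protected
#'   basis functions (constant and linear terms) are exempt from pruning.
#' @param aggregate `"mean"` or `"median"` over post-convergence windows.
#' @param K collocation points per element.
#' @param N elements per window; `NULL` = one element per `samples_per_element`
#'   data samples (capped at `N_max`).
#' @param samples_per_element,N_max grid-density knobs.
#' @param jitter relative amplitude of the seeded coefficient warm-start
#'   perturbation applied per window (identifiability probe; see
#'   [run_mho()]). 0 disables.
#' @param use_bounds apply the screening-derived coefficient bounds in the
#'   window problems (default). Disable for problems whose screen is known
#'   to be strongly biased (e.g. stiff dynamics under-resolved by the
#'   derivative estimates), where misplaced bounds pin the solve.
#' @param tol_zero numerical-resolution floor: an active pair whose median
#'   contribution to its state's right-hand side falls below
#'   `tol_zero * rms(rhs)` is treated as numerically zero at thresholding
#'   time and pruned. Scale-invariant (a contribution fraction, not a
#'   coefficient magnitude); set to the discretization-error level of the
#'   default grids.
#' @param seed master seed (solver retries).
#' @param solver list of [solve_dnlp()] options overrides.
#' @return a list of class `mhode_config`.
#' @export
mho_config <- function(H = NULL, s = NULL, omega = 3, psi = 1, Omega = 5,
                       grace = 2, aggregate = c("mean", "median"), K = 3,
                       N = NULL, samples_per_element = 12, N_max = 150,
                       jitter = 0, tol_zero = 0.005, use_bounds = TRUE,
                       seed = 1, solver = list(rho0 = 1e8)) {
  aggregate <- match.arg(aggregate)
  if (!is.null(H) && !is.null(s) && !(s > 0 && s < H)) {
    stop_mhode("need 0 < s < H", "argument")
  }
  if (omega < 1 || Omega < 1 || grace < 0 || psi <= 0) {
    stop_mhode("invalid thresholding configuration", "argument")
  }
  structure(list(H = H, s = s, omega = omega, psi = psi, Omega = Omega,
                 grace = grace, aggregate = aggregate, K = K, N = N,
                 samples_per_element = samples_per_element, N_max = N_max,
                 jitter = jitter, tol_zero = tol_zero, use_bounds = use_bounds,
                 seed = seed, solver = solver),
            class = "mhode_config")
}

# Sparse full-record refit on the active columns of the dictionary,
# used to (re-)anchor the window chain after thresholding steps.
# `Theta_full` is the dictionary evaluated on all samples and `dv_mat` the
# central-difference derivative estimates (interior rows).
anchor_estimates <- function(lib, X_int, U_int, dv_mat, c_values = NULL) {
  Theta_int <- evaluate_matrix(lib, X_int, U_int, c_values = c_values)
  Xi <- matrix(0, n_functions(lib), length(lib$state_names))
  for (j in seq_len(ncol(Xi))) {
    act <- which(lib$active[, j])
    if (length(act) == 0) next
    D <- Theta_int[, act, drop = FALSE]
    cs <- sqrt(colMeans(D^2)); cs[cs < 1e-300] <- 1
    if (length(act) == 1) {
      Xi[act, j] <- ols_minnorm(D, dv_mat[, j])$coef
    } else {
      Ds <- sweep(D, 2, cs, "/")
      Xi[act, j] <- stls_anchor(Ds, dv_mat[, j],
                                pool = !shadowed_columns(Ds))$coef / cs
    }
  }
  Xi
}

# Dominant-period heuristic for the default horizon.
estimate_horizon <- function(ts) {
  tv <- ts_times(ts)
  span <- diff(range(tv))
  x <- ts_states(ts)[, 1]
  x <- x - mean(x)
  n <- length(x)
  sp <- stats::spec.pgram(stats::ts(x, deltat = mean(diff(tv))), plot = FALSE,
                          taper = 0, detrend = TRUE)
  pk <- sp$freq[which.max(sp$spec)]
  if (is.finite(pk) && pk > 0) {
    period <- 1 / pk
    if (2 * period <= span / 3) return(2 * period)
    if (period <= span / 2) return(period)
  }
  span / 10
}

#' Coefficient of variation of a sequence of estimates
#'
#' Sample standard deviation divided by the absolute sample mean. When the
#' mean is numerically zero (|mean| < eps) the dispersion is unbounded
#' relative to the signal: the function returns `Inf`, including for a
#' consistently-zero coefficient (such a term carries no signal and should
#' be pruned). Scale-invariant: `cv(a * x) == cv(x)` for `a > 0`, which is
#' what makes thresholding independent of coefficient units and magnitudes.
#'
#' @param samples numeric vector, length >= 2.
#' @param eps zero-mean guard.
#' @return non-negative scalar (possibly `Inf`).
#' @export
coefficient_of_variation <- function(samples, eps = 1e-10) {
  if (length(samples) < 2) stop_mhode("need at least 2 samples", "argument")
  mu <- mean(samples)
  sdv <- stats::sd(samples)
  if (abs(mu) < eps) return(Inf)
  sdv / abs(mu)
}

#' Convergence rule on the active-set size trace
#'
#' @param sizes active-pair counts recorded after each thresholding step.
#' @param Omega patience.
#' @return `TRUE` iff the last `Omega + 1` entries exist and are equal.
#' @export
check_convergence <- function(sizes, Omega) {
  n <- length(sizes)
  if (n < Omega + 1) return(FALSE)
  tail_sizes <- sizes[(n - Omega):n]
  all(tail_sizes == tail_sizes[1])
}

#' One coefficient-of-variation thresholding step
#'
#' Computes the CV of every active (function, state) pair over the window
#' estimates accumulated since the last thresholding step and returns the
#' pairs to prune: those with CV strictly greater than `psi`, except
#' protected functions while `step_index <= grace`.
#'
#' @param estimates list of `Xi` matrices (full n_theta x n_x), one per
#'   window since the last thresholding step; at least 2.
#' @param lib current `mhode_library`.
#' @param cfg a [mho_config()].
#' @param step_index 1-based thresholding step counter.
#' @param col_rms optional per-function RMS of the dictionary columns over
#'   the data, and `rhs_rms` the per-state RMS of the right-hand side; when
#'   both are given, pairs whose median contribution
#'   `|coef| * col_rms` is below `cfg$tol_zero * rhs_rms` are pruned as
#'   numerically zero regardless of CV (and regardless of protection).
#' @param rhs_rms see `col_rms`.
#' @return list with `drops` (tibble `fn`, `state`) and `cv_table` (tibble
#'   `fn`, `state`, `name`, `cv`, `pruned`).
#' @export
threshold_step <- function(estimates, lib, cfg, step_index,
                           col_rms = NULL, rhs_rms = NULL) {
  if (length(estimates) < 2) stop_mhode("need >= 2 window estimates", "argument")
  pr <- active_pairs(lib)
  protected <- vapply(lib$functions, `[[`, logical(1), "protected")
  cv <- numeric(nrow(pr)); keep_protected <- logical(nrow(pr))
  below_floor <- logical(nrow(pr))
  for (q in seq_len(nrow(pr))) {
    vals <- vapply(estimates, function(m) m[pr$fn[q], pr$state[q]], numeric(1))
    cv[q] <- coefficient_of_variation(vals)
    keep_protected[q] <- protected[pr$fn[q]] && step_index <= cfg$grace
    if (!is.null(col_rms) && !is.null(rhs_rms)) {
      contrib <- stats::median(abs(vals)) * col_rms[pr$fn[q]]
      below_floor[q] <- contrib < cfg$tol_zero * rhs_rms[pr$state[q]]
    }
  }
  pruned <- (cv > cfg$psi & !keep_protected) | below_floor
  list(drops = pr[pruned, c("fn", "state")],
       cv_table = tibble::tibble(fn = pr$fn, state = pr$state,
                                 name = function_names(lib)[pr$fn],
                                 state_name = lib$state_names[pr$state],
                                 cv = cv, below_floor = below_floor,
                                 pruned = pruned))
}

#' Run moving-horizon discovery
#'
#' Slides a window of length `H` over the data in steps of `s`. Each window
#' is resampled onto a fresh collocation grid, assembled into a window
#' problem ([assemble_dnlp()]) warm-started from the previous solution, and
#' solved. Every `omega` successful windows the coefficient-of-variation
#' thresholding step prunes high-variability (function, state) pairs from
#' the dictionary; the run stops early once the active-set size has been
#' stable for `Omega` thresholding steps, and the surviving coefficients are
#' aggregated over the windows solved after the last mask change.
#'
#' @param ts smoothed [timeseries()] (run [preprocess()] first, or pass raw
#'   data at your own risk).
#' @param lib a `mhode_library` (mask possibly already screened).
#' @param cfg a [mho_config()].
#' @param screening optional `mhode_screening` supplying coefficient bounds
#'   and the first warm start.
#' @param ts_raw optional raw (unsmoothed) [timeseries()] on the same grid.
#'   When given, the window objectives fit the raw measurements -- the
#'   trajectory fit averages zero-mean noise on its own, whereas fitting
#'   the smoothed series propagates the filter's systematic peak-flattening
#'   bias into the coefficients. Smoothed data still drive screening,
#'   derivative estimates and warm starts.
#' @return list with `model` (a `mhode_model`) and `history` (a
#'   `mhode_history`: per-window estimates, objectives, statuses; per-step
#'   CV tables).
#' @export
run_mho <- function(ts, lib, cfg = mho_config(), screening = NULL,
                    ts_raw = NULL) {
  tv <- ts_times(ts)
  span <- diff(range(tv))
  H <- cfg$H %||% estimate_horizon(ts)
  s <- cfg$s %||% (H / 8)
  if (span < H) stop_mhode("data span shorter than the horizon", "data")
  if (!(s > 0 && s < H)) stop_mhode("need 0 < s < H", "argument")

  starts <- seq(tv[1], tv[length(tv)] - H + 1e-9, by = s)
  dt_med <- stats::median(diff(tv))

  # scale references shared by the jitter probe and the thresholding floor
  Theta_full <- evaluate_matrix(lib, ts_states(ts), ts_inputs(ts),
                                c_values = if (!is.null(screening$c_init))
                                  as.list(screening$c_init) else NULL)
  col_rms <- sqrt(colMeans(Theta_full^2))
  col_rms[col_rms < 1e-300] <- 1
  dv_full <- estimate_derivatives_central(ts)
  dv_mat <- as.matrix(dv_full[state_names(ts)])
  m_full <- nrow(ts)
  X_int_full <- ts_states(ts)[2:(m_full - 1), , drop = FALSE]
  U_int_full <- ts_inputs(ts)[2:(m_full - 1), , drop = FALSE]
  rhs_rms <- apply(dv_mat, 2, function(v) sqrt(mean(v^2)))
  rhs_rms[rhs_rms < 1e-300] <- 1

  since_thresh <- 0L        # successful windows since the last thresholding step
  sizes <- integer(0)
  win_rows <- list()
  cv_tables <- list()
  prev <- NULL
  n_success <- 0L
  last_change_window <- 0L
  step_index <- 0L
  converged <- FALSE
  post_est <- list(); post_c <- list(); post_windows <- integer(0)

  for (w in seq_along(starts)) {
    t0 <- starts[w]; t1 <- t0 + H
    win <- slice_window(ts, t0 - 1e-9, t1 + 1e-9)
    m_w <- nrow(win)
    N <- cfg$N %||% min(cfg$N_max, max(8, ceiling(m_w / cfg$samples_per_element)))
    grid <- build_grid(min(ts_times(win)), max(ts_times(win)), N = N, K = cfg$K)
    guesses <- initialize_guesses(win, grid, lib, screening = screening, prev = prev)
    # Identifiability probe: jitter the coefficient warm start (seeded).
    # Directions the window data pin down are pulled back to consistent
    # values by the solve; directions the data cannot identify retain the
    # window-specific jitter, inflating their coefficient of variation so
    # the thresholding step can see and prune them. The jitter scale is
    # contribution-fair: proportional to the coefficient, with a floor
    # worth a few percent of the state's right-hand-side scale.
    if (cfg$jitter > 0) {
      pr_w <- active_pairs(lib)
      floor_q <- 0.05 * rhs_rms[pr_w$state] / col_rms[pr_w$fn]
      s_q <- pmax(abs(guesses$xi), floor_q)
      u <- with_seed(cfg$seed * 1000L + w,
                     stats::runif(length(guesses$xi), -1, 1))
      guesses$xi <- guesses$xi + cfg$jitter * s_q * u
    }
    win_fit <- if (is.null(ts_raw)) win else slice_window(ts_raw, t0 - 1e-9, t1 + 1e-9)
    p <- assemble_dnlp(win_fit, lib, grid,
                       bounds = if (isTRUE(cfg$use_bounds)) screening else NULL,
                       guesses = guesses)
    sol <- solve_dnlp(p, utils::modifyList(list(seed = cfg$seed + w), cfg$solver))
    ok <- sol$status != "failed"
    win_rows[[w]] <- tibble::tibble(
      window = w, t_start = t0, t_end = t1, status = sol$status,
      objective = sol$objective, n_active = sum(lib$active),
      Xi = list(sol$Xi), c = list(sol$c)
    )
    if (!ok) next
    prev <- sol
    n_success <- n_success + 1L
    since_thresh <- since_thresh + 1L
    post_est[[length(post_est) + 1]] <- sol$Xi
    post_c[[length(post_c) + 1]] <- sol$c
    post_windows <- c(post_windows, w)

    if (since_thresh >= cfg$omega && length(post_est) >= 2) {
      step_index <- step_index + 1L
      # CV pooled over every successful window since the last mask change:
      # slowly wandering spurious coefficients accumulate dispersion across
      # batches, while identifiable terms stay tight however long the pool.
      th <- threshold_step(post_est, lib, cfg, step_index,
                           col_rms = col_rms, rhs_rms = rhs_rms)
      cv_tables[[step_index]] <- dplyr::mutate(th$cv_table, step = step_index,
                                               window = w)
      if (nrow(th$drops) > 0) {
        lib <- prune(lib, th$drops)
        last_change_window <- w
        prev_batch <- list(est = post_est, c = post_c, windows = post_windows)
        post_est <- list(); post_c <- list(); post_windows <- integer(0)
      }
      sizes <- c(sizes, sum(lib$active))
      since_thresh <- 0L
      if (check_convergence(sizes, cfg$Omega)) { converged <- TRUE }
      # Re-anchor the warm-start chain on the reduced dictionary: a sparse
      # full-record refit recenters the next windows at the best current
      # structure, so a chain captured by a locally self-consistent set of
      # spurious terms is pulled out once its partners are pruned.
      if (!is.null(prev)) {
        cv_now <- if (length(prev$c) > 0) as.list(prev$c) else NULL
        re <- tryCatch(anchor_estimates(lib, X_int_full, U_int_full, dv_mat,
                                        c_values = cv_now),
                       error = function(e) NULL)
        if (!is.null(re)) prev$Xi <- re
      }
    }
    if (converged && length(post_est) >= 1) break
  }

  history <- structure(list(
    windows = dplyr::bind_rows(win_rows),
    cv = if (length(cv_tables)) dplyr::bind_rows(cv_tables) else tibble::tibble(),
    sizes = sizes, converged = converged,
    H = H, s = s, post_windows = post_windows
  ), class = "mhode_history")

  if (length(post_est) == 0 && exists("prev_batch") && length(prev_batch$est) > 0) {
    # the record ended immediately after a mask change: fall back to the
    # estimates that fed the final thresholding step (restricted to the
    # surviving pairs at aggregation time)
    post_est <- prev_batch$est; post_c <- prev_batch$c
    post_windows <- prev_batch$windows
    history$post_windows <- post_windows
  }
  if (length(post_est) == 0) {
    stop_mhode("no successful post-convergence window; discovery failed", "discovery")
  }
  model <- aggregate_model_internal(post_est, post_c, post_windows, lib, cfg,
                                    converged, history)
  list(model = model, history = history)
}

#' Aggregate window estimates into a discovered model
#'
#' Point estimate per surviving coefficient (and nonlinear parameter) is the
#' mean or median over the post-convergence windows; intervals are the
#' empirical 2.5/97.5 percentiles (collapsing to the point estimate when
#' only one window is available). Pruned pairs are rendered as exact zeros.
#'
#' @param history a `mhode_history` from [run_mho()].
#' @param lib the (pruned) `mhode_library`.
#' @param cfg a [mho_config()].
#' @return a `mhode_model`.
#' @export
aggregate_model <- function(history, lib, cfg) {
  pw <- history$post_windows
  if (length(pw) == 0) stop_mhode("empty post-convergence history", "aggregation")
  rows <- history$windows[history$windows$window %in% pw, ]
  aggregate_model_internal(rows$Xi, rows$c, pw, lib, cfg, history$converged, history)
}

aggregate_model_internal <- function(est_list, c_list, windows, lib, cfg,
                                     converged, history = NULL) {
  agg_fun <- if (cfg$aggregate == "median") stats::median else mean
  pr <- active_pairs(lib)
  nx <- length(lib$state_names)
  Xi <- matrix(0, n_functions(lib), nx,
               dimnames = list(function_names(lib), lib$state_names))
  lo <- Xi; hi <- Xi
  coef_rows <- vector("list", nrow(pr))
  for (q in seq_len(nrow(pr))) {
    vals <- vapply(est_list, function(m) m[pr$fn[q], pr$state[q]], numeric(1))
    pt <- agg_fun(vals)
    qs <- if (length(vals) > 1) stats::quantile(vals, c(0.025, 0.975), names = FALSE) else c(pt, pt)
    Xi[pr$fn[q], pr$state[q]] <- pt
    lo[pr$fn[q], pr$state[q]] <- qs[1]
    hi[pr$fn[q], pr$state[q]] <- qs[2]
    coef_rows[[q]] <- tibble::tibble(
      term = function_names(lib)[pr$fn[q]], state = lib$state_names[pr$state[q]],
      estimate = pt, conf.low = qs[1], conf.high = qs[2], n_windows = length(vals)
    )
  }
  ptab <- lib_param_table(lib)
  c_est <- numeric(0); c_tab <- tibble::tibble()
  if (nrow(ptab) > 0) {
    cm <- do.call(rbind, c_list)
    c_est <- stats::setNames(apply(cm, 2, agg_fun), ptab$name)
    c_tab <- tibble::tibble(
      param = ptab$name, estimate = unname(c_est),
      conf.low = apply(cm, 2, function(v) if (length(v) > 1) stats::quantile(v, 0.025, names = FALSE) else v),
      conf.high = apply(cm, 2, function(v) if (length(v) > 1) stats::quantile(v, 0.975, names = FALSE) else v)
    )
  }
  structure(list(
    coefficients = dplyr::bind_rows(coef_rows),
    c_params = c_tab, c = c_est,
    Xi = Xi, Xi_low = lo, Xi_high = hi,
    library = lib, equations = render_equations(lib, Xi, c_est),
    provenance = windows, converged = converged, aggregate = cfg$aggregate
  ), class = "mhode_model")
}

render_equations <- function(lib, Xi, c_est) {
  eqs <- character(ncol(Xi))
  for (j in seq_len(ncol(Xi))) {
    act <- which(Xi[, j] != 0)
    if (length(act) == 0) { eqs[j] <- paste0("d", lib$state_names[j], "/dt = 0"); next }
    terms <- vapply(act, function(i) {
      txt <- lib$functions[[i]]$text
      for (p in names(c_est)) {
        txt <- gsub(paste0("\\b", p, "\\b"), format(c_est[[p]], digits = 8), txt)
      }
      co <- format(Xi[i, j], digits = 8)
      if (txt == "1") co else paste0(co, "*", txt)
    }, character(1))
    eqs[j] <- paste0("d", lib$state_names[j], "/dt = ", paste(terms, collapse = " + "))
  }
  eqs
}

#' Simulate a discovered model
#'
#' Integrates the aggregated right-hand side with a stiff-capable adaptive
#' integrator (deSolve lsoda, rtol 1e-8).
#'
#' @param model a `mhode_model`.
#' @param x0 initial state (named or positional).
#' @param t_grid output time points.
#' @param input_fn optional function `t -> named input values`.
#' @return a [timeseries()] tibble of the simulated states.
#' @export
simulate_model <- function(model, x0, t_grid, input_fn = NULL) {
  lib <- model$library
  snames <- lib$state_names
  cl <- as.list(model$c)
  rhs <- function(t, y, parms) {
    stm <- matrix(y, nrow = 1)
    um <- if (length(lib$input_names) > 0) {
      matrix(as.numeric(input_fn(t)), nrow = 1)
    } else {
      matrix(numeric(0), nrow = 1, ncol = 0)
    }
    th <- tryCatch(evaluate_matrix(lib, stm, um, cl), error = function(e) NULL)
    if (is.null(th)) return(list(rep(NA_real_, length(y))))
    list(as.numeric(th %*% model$Xi))
  }
  out <- deSolve::ode(y = stats::setNames(as.numeric(x0), snames), times = t_grid,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  if (nrow(out) < length(t_grid) || any(!is.finite(out))) {
    stop_mhode(paste0("integration of the discovered model failed near t = ",
                      round(out[nrow(out), 1], 4)), "simulation")
  }
  df <- tibble::as_tibble(as.data.frame(out))
  names(df)[1] <- "t"
  timeseries(df, time = "t", states = snames)
}

#' Mean squared error between two trajectories on a shared grid
#'
#' @param a,b [timeseries()] objects (or matrices) with identical shapes.
#' @return mean over all points and states of squared differences.
#' @export
trajectory_mse <- function(a, b) {
  A <- if (inherits(a, "mhode_ts")) ts_states(a) else as.matrix(a)
  B <- if (inherits(b, "mhode_ts")) ts_states(b) else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop_mhode("trajectory shapes differ", "argument")
  mean((A - B)^2)
}
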