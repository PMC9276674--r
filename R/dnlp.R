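#' Assemble the discretized dynamic nonlinear program for one data window
#'
#' Builds the simultaneous-collocation estimation problem: decision
#' variables are the coefficient matrix entries (active pairs only), the
#' nonlinear basis parameters `c`, and the state values at every collocation
#' node. The objective is the mean squared mismatch between the predicted
#' states and the (smoothed, spline-resampled) data at the nodes,
#' \eqn{\frac{1}{2NK}\sum_{ij} \|x(t_{ij}) - \tilde x(t_{ij})\|^2}, plus an
#' optional regularization term. The constraints are the Lagrange-Radau
#' collocation equations with right-hand side \eqn{\Xi^T \Theta(x(t_{ij}),
#' \tilde u(t_{ij}), c)^T} evaluated on the *decision-variable* states --
#' never on the data -- plus element-continuity equations and variable
#' bounds. Inputs are fixed data resampled onto the nodes.
#'
#' @param window a smoothed [timeseries()] covering the grid (>= 4 samples).
#' @param lib a `mhode_library`; only active pairs become variables.
#' @param grid a [build_grid()] lying inside the window's time range.
#' @param bounds a `mhode_screening` object, or a list with matrices
#'   `lower`/`upper` (n_theta x n_x); `NULL` means unbounded coefficients.
#' @param reg list `(kind = "none"|"l1"|"l2", lambda)`; default no
#'   regularization (sparsity comes from thresholding, not the objective).
#' @param guesses list with `states` (node values), `xi` (per active pair),
#'   `c`; see [initialize_guesses()]. Guesses outside bounds are clipped
#'   with a warning.
#' @return an object of class `mhode_dnlp`.
#' @export
assemble_dnlp <- function(window, lib, grid, bounds = NULL,
                          reg = list(kind = "none", lambda = 0),
                          guesses = NULL) {
  trange <- range(ts_times(window))
  if (grid$boundaries[1] < trange[1] - 1e-9 ||
      grid$boundaries[length(grid$boundaries)] > trange[2] + 1e-9) {
    stop_mhode("collocation grid exceeds the data window", "range")
  }
  if (nrow(window) < 4) stop_mhode("window too short to resample", "insufficient_data")

  N <- grid$N; K <- grid$K
  nx <- length(lib$state_names)
  pairs <- active_pairs(lib)
  if (nrow(pairs) == 0) stop_mhode("library has no active pairs", "argument")
  fidx <- sort(unique(pairs$fn))
  pairs$fpos <- match(pairs$fn, fidx)
  ptab <- lib_param_table(lib)
  nc <- nrow(ptab)

  n_nodes <- N * (K + 1)
  n_int <- N * K
  n_sv <- n_nodes * nx
  n_pairs <- nrow(pairs)
  n_z <- n_sv + n_pairs + nc

  # node bookkeeping: node a = (i-1)(K+1) + k + 1, k = 0..K
  all_t <- as.vector(t(grid$times))            # ordered by i, then k
  a_int <- as.vector(t(matrix(seq_len(n_nodes), ncol = K + 1, byrow = TRUE)[, -1, drop = FALSE]))
  # a_int ordered (i, j): row (i-1)K + j

  rs <- resample(window, grid$node_times)
  pos <- match(round(all_t, 10), round(grid$node_times, 10))
  xtil <- ts_states(rs)[pos, , drop = FALSE]
  util_int <- ts_inputs(rs)[pos[a_int], , drop = FALSE]

  # per-state nondimensionalization: states measured in hundreds of units
  # must not drown states of order one, so mismatch and constraint rows are
  # weighted by the inverse RMS of each state's window data (the reported
  # objective stays in raw units)
  state_scale <- pmax(sqrt(colMeans(xtil^2)), 1e-8)

  # bounds per decision variable
  lb <- rep(-Inf, n_z); ub <- rep(Inf, n_z)
  if (!is.null(bounds)) {
    blo <- bounds$lower; bup <- bounds$upper
    for (p in seq_len(n_pairs)) {
      l <- blo[pairs$fn[p], pairs$state[p]]; u <- bup[pairs$fn[p], pairs$state[p]]
      if (is.finite(l) && is.finite(u) && l > u) stop_mhode("inconsistent coefficient bounds", "argument")
      if (!is.na(l)) lb[n_sv + p] <- l
      if (!is.na(u)) ub[n_sv + p] <- u
    }
  }
  if (nc > 0) {
    lb[n_sv + n_pairs + seq_len(nc)] <- ptab$lower
    ub[n_sv + n_pairs + seq_len(nc)] <- ptab$upper
  }

  if (is.null(guesses)) {
    guesses <- list(states = xtil, xi = rep(0, n_pairs), c = ptab$init)
  }
  z0 <- numeric(n_z)
  z0[seq_len(n_sv)] <- as.vector(guesses$states)
  z0[n_sv + seq_len(n_pairs)] <- guesses$xi
  if (nc > 0) z0[n_sv + n_pairs + seq_len(nc)] <- guesses$c
  if (any(z0 < lb - 1e-12) || any(z0 > ub + 1e-12)) {
    warn_mhode("initial guess outside bounds; clipped", "clip")
  }
  z0 <- pmin(pmax(z0, lb), ub)

  # precompiled evaluation plan: expressions and their partials for the
  # functions in use, aligned to the global parameter order (hot path --
  # avoids any per-iteration library bookkeeping)
  plan <- list(
    snames = lib$state_names, inames = lib$input_names, pnames = ptab$name,
    exprs = lapply(lib$functions[fidx], `[[`, "expr"),
    dxs = lapply(lib$functions[fidx], `[[`, "dx"),
    dcs = lapply(lib$functions[fidx], function(bf) {
      out <- vector("list", nc)
      if (nrow(bf$params) > 0) {
        out[match(bf$params$name, ptab$name)] <- bf$dc[bf$params$name]
      }
      out
    })
  )

  structure(list(
    grid = grid, lib = lib, pairs = pairs, fidx = fidx, ptab = ptab,
    plan = plan,
    nx = nx, N = N, K = K, n_nodes = n_nodes, n_int = n_int,
    n_sv = n_sv, n_pairs = n_pairs, nc = nc, n_z = n_z,
    a_int = a_int, xtil = xtil, util_int = util_int,
    state_scale = state_scale,
    lb = lb, ub = ub, z0 = z0, reg = reg,
    w_mis = 1 / (2 * N * K),
    state_names = lib$state_names
  ), class = "mhode_dnlp")
}

#' @export
print.mhode_dnlp <- function(x, ...) {
  cat(sprintf("<mhode_dnlp> %d state vars + %d coefficients + %d parameters; %d constraints\n",
              x$n_sv, x$n_pairs, x$nc, x$n_int * x$nx + (x$N - 1) * x$nx))
  invisible(x)
}

#' Warm-start guesses for a window
#'
#' States are initialized by spline-resampling the smoothed data onto the
#' grid nodes; coefficients come from the previous window's solution when
#' available, else from the OLS screen; nonlinear parameters from the
#' previous solution, else the midpoint of their bounds.
#'
#' @param window smoothed [timeseries()].
#' @param grid a [build_grid()].
#' @param lib a `mhode_library`.
#' @param screening optional `mhode_screening` (first window).
#' @param prev optional previous `mhode_dnlp_solution`.
#' @return guess list for [assemble_dnlp()].
#' @export
initialize_guesses <- function(window, grid, lib, screening = NULL, prev = NULL) {
  rs <- resample(window, grid$node_times)
  all_t <- as.vector(t(grid$times))
  pos <- match(round(all_t, 10), round(grid$node_times, 10))
  states <- ts_states(rs)[pos, , drop = FALSE]
  pairs <- active_pairs(lib)
  ptab <- lib_param_table(lib)
  xi <- numeric(nrow(pairs))
  if (!is.null(prev)) {
    xi <- prev$Xi[cbind(pairs$fn, pairs$state)]
  } else if (!is.null(screening)) {
    src <- screening$xi_init %||% screening$xi_ols
    xi <- src[cbind(pairs$fn, pairs$state)]
    xi[is.na(xi)] <- 0
  }
  cg <- if (!is.null(prev) && length(prev$c) == nrow(ptab)) {
    prev$c
  } else if (!is.null(screening$c_init) && length(screening$c_init) == nrow(ptab)) {
    screening$c_init
  } else if (nrow(ptab) > 0) {
    stats::setNames((ptab$lower + ptab$upper) / 2, ptab$name)
  } else {
    numeric(0)
  }
  list(states = states, xi = xi, c = cg)
}

# ---- residuals and Jacobian ----------------------------------------------

# Fast dictionary evaluation for the solver: values and partials of the
# in-use basis functions at the interior nodes, from the precompiled plan.
plan_eval <- function(plan, states, inputs, c_values) {
  m <- nrow(states)
  env <- new.env(parent = baseenv())
  for (j in seq_along(plan$snames)) assign(plan$snames[j], states[, j], envir = env)
  for (j in seq_along(plan$inames)) assign(plan$inames[j], inputs[, j], envir = env)
  for (j in seq_along(plan$pnames)) assign(plan$pnames[j], c_values[[j]], envir = env)
  nf <- length(plan$exprs)
  nx <- length(plan$snames)
  nc <- length(plan$pnames)
  theta <- matrix(0, m, nf)
  dxa <- array(0, dim = c(m, nf, nx))
  dca <- if (nc > 0) array(0, dim = c(m, nf, nc)) else NULL
  for (q in seq_len(nf)) {
    theta[, q] <- eval(plan$exprs[[q]], envir = env)
    dxq <- plan$dxs[[q]]
    for (j in seq_len(nx)) dxa[, q, j] <- eval(dxq[[j]], envir = env)
    if (nc > 0) {
      dcq <- plan$dcs[[q]]
      for (j in seq_len(nc)) {
        if (!is.null(dcq[[j]])) dca[, q, j] <- eval(dcq[[j]], envir = env)
      }
    }
  }
  list(theta = theta, dx = dxa, dc = dca)
}

# Raw (unweighted) residuals at z: list(mis, con) where `con` stacks the
# collocation derivative-match rows (state-major, then element, then node)
# and the continuity rows.
dnlp_resid <- function(p, z) {
  N <- p$N; K <- p$K; nx <- p$nx
  X <- matrix(z[seq_len(p$n_sv)], p$n_nodes, nx)
  xi <- z[p$n_sv + seq_len(p$n_pairs)]
  cv <- if (p$nc > 0) stats::setNames(z[p$n_sv + p$n_pairs + seq_len(p$nc)], p$ptab$name) else NULL
  Xint <- X[p$a_int, , drop = FALSE]
  ev <- plan_eval(p$plan, Xint, p$util_int, cv)
  if (any(!is.finite(ev$theta))) return(NULL)
  Xi <- matrix(0, length(p$fidx), nx)
  Xi[cbind(p$pairs$fpos, p$pairs$state)] <- xi
  Fint <- ev$theta %*% Xi                     # n_int x nx
  Dr <- p$grid$D[2:(K + 1), , drop = FALSE]
  h <- p$grid$h[1]
  con1 <- numeric(nx * p$n_int)
  for (s in seq_len(nx)) {
    Xel <- t(matrix(X[, s], nrow = K + 1))    # N x (K+1)
    Ms <- (Xel %*% t(Dr)) / h                 # N x K
    con1[(s - 1) * p$n_int + seq_len(p$n_int)] <- as.vector(t(Ms)) - Fint[, s]
  }
  con2 <- numeric(0)
  if (N > 1) {
    lend <- p$grid$lend
    for (s in seq_len(nx)) {
      Xel <- t(matrix(X[, s], nrow = K + 1))
      iend <- as.vector(Xel %*% lend)
      con2 <- c(con2, Xel[2:N, 1] - iend[1:(N - 1)])
    }
  }
  list(mis = as.vector(X - p$xtil), con = c(con1, con2), ev = ev, Xi = Xi, X = X)
}

# Sparsity pattern (row/col indices) of the weighted Jacobian; computed once
# per problem. Row order: [mismatch | collocation | continuity].
dnlp_pattern <- function(p) {
  N <- p$N; K <- p$K; nx <- p$nx
  n_mis <- p$n_sv
  n_c1 <- nx * p$n_int
  n_c2 <- if (N > 1) nx * (N - 1) else 0
  idx_state <- function(a, s) (s - 1) * p$n_nodes + a

  n_int <- p$n_int
  ii <- list(); jj <- list()
  # mismatch block: row r corresponds to state var r (same ordering)
  ii$mis <- seq_len(n_mis); jj$mis <- seq_len(n_mis)

  # collocation, derivative part: row (s,i,j) x cols (i,k,s)
  base_a <- rep(seq_len(K + 1), times = K)             # per element, j fastest
  elem_off <- rep((0:(N - 1)) * (K + 1), each = K * (K + 1))
  cols0 <- elem_off + rep(base_a, N)
  rows0 <- rep(seq_len(n_int), each = K + 1)
  ii$cola <- n_mis + rep((0:(nx - 1)) * n_int, each = length(rows0)) + rep(rows0, nx)
  jj$cola <- rep((0:(nx - 1)) * p$n_nodes, each = length(cols0)) + rep(cols0, nx)
  vals_a <- rep(as.vector(t(p$grid$D[2:(K + 1), , drop = FALSE] / p$grid$h[1])),
                times = nx * N)

  # collocation, -d(Xi' theta)/dx part: blocks over (row-state s, col-state sp)
  s_seq <- rep(seq_len(nx), each = nx)
  sp_seq <- rep(seq_len(nx), times = nx)
  ii$colb <- n_mis + rep((s_seq - 1) * n_int, each = n_int) + rep(seq_len(n_int), nx * nx)
  jj$colb <- rep((sp_seq - 1) * p$n_nodes, each = n_int) + rep(p$a_int, nx * nx)

  # collocation, -theta part (coefficient columns)
  ii$colc <- n_mis + rep((p$pairs$state - 1) * n_int, each = n_int) +
    rep(seq_len(n_int), p$n_pairs)
  jj$colc <- rep(p$n_sv + seq_len(p$n_pairs), each = n_int)

  # collocation, -Xi' dtheta/dc part: blocks over (parameter q, row-state s)
  ii$cold <- integer(0); jj$cold <- integer(0)
  if (p$nc > 0) {
    q_seq <- rep(seq_len(p$nc), each = nx)
    s_seq2 <- rep(seq_len(nx), times = p$nc)
    ii$cold <- n_mis + rep((s_seq2 - 1) * n_int, each = n_int) +
      rep(seq_len(n_int), p$nc * nx)
    jj$cold <- rep(p$n_sv + p$n_pairs + q_seq, each = n_int)
  }

  # continuity rows
  rows_e <- integer(0); cols_e <- integer(0); vals_e <- numeric(0)
  if (N > 1) {
    lend <- p$grid$lend
    for (s in seq_len(nx)) {
      for (i in seq_len(N - 1)) {
        r <- n_mis + n_c1 + (s - 1) * (N - 1) + i
        a_next0 <- i * (K + 1) + 1
        a_prev <- (i - 1) * (K + 1) + seq_len(K + 1)
        rows_e <- c(rows_e, r, rep(r, K + 1))
        cols_e <- c(cols_e, idx_state(a_next0, s), idx_state(a_prev, s))
        vals_e <- c(vals_e, 1, -lend)
      }
    }
  }
  ii$cole <- rows_e; jj$cole <- cols_e

  # per-row state weights (nondimensionalization)
  inv_s <- 1 / p$state_scale
  ws <- c(rep(inv_s, each = p$n_nodes),
          rep(inv_s, each = n_int),
          if (N > 1) rep(inv_s, each = N - 1) else numeric(0))

  list(ii = unlist(ii, use.names = FALSE), jj = unlist(jj, use.names = FALSE),
       n_rows = n_mis + n_c1 + n_c2, n_mis = n_mis, n_con = n_c1 + n_c2,
       vals_a = vals_a, vals_e = vals_e,
       ws_mis = ws[seq_len(n_mis)], ws_con = ws[n_mis + seq_len(n_c1 + n_c2)],
       ws = ws)
}

# Value vector matching dnlp_pattern ordering, from a dnlp_resid() result.
dnlp_jac_vals <- function(p, pat, rr) {
  nx <- p$nx
  vals_mis <- rep(1, pat$n_mis)
  # block b: for each (row-state s, col-state sp): -dtheta/dx_sp %*% Xi[, s]
  A <- lapply(seq_len(nx), function(sp) rr$ev$dx[, , sp, drop = FALSE][, , 1] %*% rr$Xi)
  vb_list <- vector("list", nx * nx)
  k <- 0
  for (s in seq_len(nx)) {
    for (sp in seq_len(nx)) {
      k <- k + 1
      vb_list[[k]] <- -as.vector(A[[sp]][, s])
    }
  }
  vb <- unlist(vb_list, use.names = FALSE)
  # block c: -theta columns per pair (column-major flatten matches pattern)
  vc <- -as.vector(rr$ev$theta[, p$pairs$fpos, drop = FALSE])
  # block d: per parameter q, per row-state s
  vd <- numeric(0)
  if (p$nc > 0) {
    vd_list <- vector("list", p$nc * nx)
    k <- 0
    for (q in seq_len(p$nc)) {
      Aq <- rr$ev$dc[, , q, drop = FALSE][, , 1] %*% rr$Xi
      for (s in seq_len(nx)) {
        k <- k + 1
        vd_list[[k]] <- -as.vector(Aq[, s])
      }
    }
    vd <- unlist(vd_list, use.names = FALSE)
  }
  c(vals_mis, pat$vals_a, vb, vc, vd, pat$vals_e)
}

# ---- solver ---------------------------------------------------------------

#' Solve an assembled window problem
#'
#' Augmented-Lagrangian outer iterations drive the collocation equality
#' constraints to feasibility; each subproblem is a bound-projected
#' Levenberg-Marquardt minimization of the stacked residual system with
#' analytic sparse Jacobians. On failure the solve is retried once from a
#' 1\%-perturbed guess (seeded), then reported as failed.
#'
#' @param p a `mhode_dnlp` from [assemble_dnlp()].
#' @param opts list of solver options: `feas_tol` (default 1e-8), `opt_tol`
#'   (1e-8), `max_outer` (12), `max_iter` (inner LM iterations per outer,
#'   default 80), `rho0` (initial constraint penalty; the default 1e4 ramps
#'   up classically, good for rough warm starts -- the moving-horizon
#'   driver overrides this to 1e8 so that iterates stay on the dynamics
#'   manifold from the first step, see [mho_config()]), `seed` (retry
#'   perturbation).
#' @return an object of class `mhode_dnlp_solution`: `Xi` (full n_theta x
#'   n_x matrix, exact zeros at inactive pairs), `c`, `states` (node
#'   values), `objective` (data-mismatch objective plus regularization),
#'   `status` (`"optimal"`, `"locally-optimal"` or `"failed"`),
#'   `constraint_violation` and `iterations`.
#' @export
solve_dnlp <- function(p, opts = list()) {
  o <- utils::modifyList(list(feas_tol = 1e-8, opt_tol = 1e-8, max_outer = 12,
                              max_iter = 80, rho0 = 1e4, seed = 1, verbose = FALSE),
                         opts)
  res <- dnlp_solve_attempt(p, p$z0, o)
  if (res$status == "failed") {
    z0 <- with_seed(o$seed, p$z0 * (1 + 0.01 * stats::rnorm(p$n_z)))
    z0 <- pmin(pmax(z0, p$lb), p$ub)
    res2 <- dnlp_solve_attempt(p, z0, o)
    if (res2$status != "failed") res <- res2
  }
  res
}

dnlp_solve_attempt <- function(p, z0, o) {
  pat <- dnlp_pattern(p)
  n_mis <- pat$n_mis; n_con <- pat$n_con
  sqw <- sqrt(p$w_mis)
  lam <- numeric(n_con)
  rho <- o$rho0
  z <- z0
  viol_prev <- Inf
  total_iter <- 0L
  status <- "failed"

  reg_scale <- p$reg$scale %||% rep(1, p$n_pairs)
  reg_resid <- function(xi) {
    if (p$reg$kind == "l2" && p$reg$lambda > 0) {
      list(r = sqrt(p$reg$lambda) * xi / reg_scale,
           d = sqrt(p$reg$lambda) / reg_scale)
    } else if (p$reg$kind == "l1" && p$reg$lambda > 0) {
      # smoothed |xi| ~ sqrt(xi^2 + eps); residual sqrt(lambda)*(xi^2+eps)^(1/4)
      eps <- 1e-10
      r <- sqrt(p$reg$lambda) * (xi^2 + eps)^0.25
      d <- sqrt(p$reg$lambda) * 0.5 * xi * (xi^2 + eps)^(-0.75)
      list(r = r, d = d)
    } else {
      NULL
    }
  }

  weighted <- function(z, lam, rho) {
    rr <- dnlp_resid(p, z)
    if (is.null(rr)) return(NULL)
    srho <- sqrt(rho / 2)
    con_s <- rr$con * pat$ws_con      # nondimensionalized constraints
    rfull <- c(sqw * rr$mis * pat$ws_mis, srho * (con_s + lam / rho))
    rg <- reg_resid(z[p$n_sv + seq_len(p$n_pairs)])
    if (!is.null(rg)) rfull <- c(rfull, rg$r)
    if (any(!is.finite(rfull))) return(NULL)
    list(rr = rr, con_s = con_s, rfull = rfull, cost = sum(rfull^2),
         rg = rg, srho = srho)
  }

  h_diag_pos <- NULL
  chol_sym <- NULL
  for (outer in seq_len(o$max_outer)) {
    wv <- weighted(z, lam, rho)
    if (is.null(wv)) break
    mu <- 1e-6
    iter_done <- FALSE
    for (iter in seq_len(o$max_iter)) {
      total_iter <- total_iter + 1L
      vals <- dnlp_jac_vals(p, pat, wv$rr)
      rw <- c(rep(sqw, n_mis), rep(wv$srho, n_con)) * pat$ws
      ii <- pat$ii; jj <- pat$jj
      vals <- vals * rw[ii]
      nrows <- pat$n_rows
      if (!is.null(wv$rg)) {
        extra_r <- nrows + seq_len(p$n_pairs)
        ii <- c(ii, extra_r)
        jj <- c(jj, p$n_sv + seq_len(p$n_pairs))
        vals <- c(vals, wv$rg$d)
        nrows <- nrows + p$n_pairs
      }
      J <- Matrix::sparseMatrix(i = ii, j = jj, x = vals, dims = c(nrows, p$n_z))
      g <- as.numeric(Matrix::crossprod(J, wv$rfull))
      H <- Matrix::crossprod(J)
      dH <- pmax(Matrix::diag(H), 1e-10)
      # in-place Marquardt damping: locate the stored diagonal entries once
      # (the sparsity pattern of J'J is fixed across iterations) and reuse
      # the symbolic Cholesky factorization
      if (is.null(h_diag_pos)) {
        dp <- integer(p$n_z)
        cp <- H@p; ri <- H@i
        for (col in seq_len(p$n_z)) {
          rng <- seq.int(cp[col] + 1L, cp[col + 1L])
          dp[col] <- rng[match(col - 1L, ri[rng])]
        }
        if (anyNA(dp)) {        # structurally absent diagonal: keep fallback
          h_diag_pos <- integer(0)
        } else {
          h_diag_pos <- dp
          chol_sym <- tryCatch(Matrix::Cholesky(H, LDL = FALSE, Imult = 1e-8),
                               error = function(e) NULL)
        }
      }
      accepted <- FALSE
      for (try in 1:25) {
        if (length(h_diag_pos) == p$n_z) {
          M <- H
          M@x[h_diag_pos] <- H@x[h_diag_pos] + mu * dH
        } else {
          M <- H + Matrix::Diagonal(x = mu * dH)
        }
        delta <- tryCatch({
          if (!is.null(chol_sym)) {
            fac <- Matrix::update(chol_sym, M)
            as.numeric(Matrix::solve(fac, -g))
          } else {
            as.numeric(Matrix::solve(M, -g))
          }
        }, error = function(e) NULL)
        if (is.null(delta) || any(!is.finite(delta))) { mu <- mu * 10; next }
        znew <- pmin(pmax(z + delta, p$lb), p$ub)
        wnew <- weighted(znew, lam, rho)
        if (!is.null(wnew) && is.finite(wnew$cost) && wnew$cost < wv$cost) {
          step <- max(abs(znew - z))
          rel_drop <- (wv$cost - wnew$cost) / max(wv$cost, 1e-300)
          z <- znew; wv <- wnew
          mu <- max(mu / 3, 1e-12)
          accepted <- TRUE
          iter_done <- step < 1e-11 * (1 + max(abs(z))) || rel_drop < 1e-14
          break
        }
        mu <- mu * 4
        if (mu > 1e13) break
      }
      if (!accepted || iter_done) break
    }
    viol <- max(abs(wv$con_s))
    if (viol < o$feas_tol) { status <- "optimal"; break }
    lam <- lam + rho * wv$con_s
    if (viol > 0.25 * viol_prev) rho <- min(rho * 10, 1e12)
    viol_prev <- viol
  }

  rr <- dnlp_resid(p, z)
  viol <- if (is.null(rr)) Inf else max(abs(rr$con * pat$ws_con))
  if (status == "failed" && is.finite(viol) &&
      viol < max(1e-6, 100 * o$feas_tol)) {
    status <- "locally-optimal"
  }
  Xi_full <- matrix(0, n_functions(p$lib), p$nx,
                    dimnames = list(function_names(p$lib), p$state_names))
  cvec <- numeric(0)
  obj <- NA_real_
  if (!is.null(rr)) {
    Xi_full[cbind(p$pairs$fn, p$pairs$state)] <- z[p$n_sv + seq_len(p$n_pairs)]
    cvec <- if (p$nc > 0) stats::setNames(z[p$n_sv + p$n_pairs + seq_len(p$nc)], p$ptab$name) else numeric(0)
    obj <- p$w_mis * sum(rr$mis^2)
    if (p$reg$kind == "l2" && p$reg$lambda > 0) {
      obj <- obj + p$reg$lambda * sum((z[p$n_sv + seq_len(p$n_pairs)] / (p$reg$scale %||% 1))^2)
    }
    if (p$reg$kind == "l1" && p$reg$lambda > 0) obj <- obj + p$reg$lambda * sum(abs(rr$Xi))
  }
  structure(list(Xi = Xi_full, c = cvec,
                 states = if (is.null(rr)) NULL else rr$X,
                 objective = obj, status = status,
                 constraint_violation = viol, iterations = total_iter),
            class = "mhode_dnlp_solution")
}

#' @export
print.mhode_dnlp_solution <- function(x, ...) {
  cat(sprintf("<mhode_dnlp_solution> status=%s, objective=%.3e, |g|=%.1e, %d LM iterations\n",
              x$status, x$objective, x$constraint_violation, x$iterations))
  invisible(x)
}
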