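#' Radau IIA collocation abscissas on (0, 1]
#'
#' The K Gauss-Radau points with the right endpoint included (the last point
#' is exactly 1). The interior points are the Gauss-Jacobi nodes for weight
#' \eqn{(1-x)} on \eqn{[-1,1]} (Golub-Welsch eigenvalue method), mapped to
#' (0, 1). Including the right endpoint makes the element-continuity
#' equation trivial and confers A-stability, which suits stiff dynamics.
#'
#' @param K number of collocation points per element (1..10).
#' @return strictly increasing numeric vector of length K, last entry 1.
#' @examples
#' radau_points(2)  # 1/3, 1
#' @export
radau_points <- function(K) {
  if (!(K >= 1 && K <= 10)) stop_mhode("K must be between 1 and 10", "argument")
  if (K == 1) return(1)
  n <- K - 1
  # Jacobi(alpha=1, beta=0) recurrence (monic), Golub-Welsch.
  a <- 1; b <- 0
  kk <- 0:(n - 1)
  diag_t <- (b^2 - a^2) / ((2 * kk + a + b) * (2 * kk + a + b + 2))
  if (n > 1) {
    k2 <- 1:(n - 1)
    off2 <- 4 * k2 * (k2 + a) * (k2 + b) * (k2 + a + b) /
      ((2 * k2 + a + b)^2 * (2 * k2 + a + b + 1) * (2 * k2 + a + b - 1))
    J <- diag(diag_t)
    for (i in seq_len(n - 1)) {
      J[i, i + 1] <- sqrt(off2[i])
      J[i + 1, i] <- sqrt(off2[i])
    }
    nodes <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  } else {
    nodes <- diag_t
  }
  tau <- (nodes + 1) / 2
  # Newton-polish on the Radau polynomial P_{K-1}(2t-1) - P_K(2t-1) = 0
  # (right-endpoint Gauss-Radau: x = +1 plus the K-1 interior roots)
  legendre <- function(nn, x) {
    p0 <- rep(1, length(x)); if (nn == 0) return(list(p = p0, dp = rep(0, length(x))))
    p1 <- x
    for (k in 2:max(nn, 2)) {
      if (k > nn) break
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    p <- if (nn == 1) x else p1
    pm1 <- if (nn == 1) rep(1, length(x)) else p0
    dp <- nn * (x * p - pm1) / (x^2 - 1)
    list(p = p, dp = dp)
  }
  for (it in 1:50) {
    x <- 2 * tau - 1
    lk <- legendre(K, x); lk1 <- legendre(K - 1, x)
    f <- lk1$p - lk$p
    df <- 2 * (lk1$dp - lk$dp)
    step <- f / df
    tau <- tau - step
    if (max(abs(step)) < 1e-15) break
  }
  c(sort(tau), 1)
}

#' Lagrange interpolation derivative table
#'
#' For interpolation nodes `taus` (\eqn{\tau_0 ... \tau_K}), returns the
#' differentiation matrix `D` with \eqn{D[j, k] = d\ell_k/d\tau} evaluated at
#' \eqn{\tau_j} (rows over all nodes), and the weights \eqn{\ell_k(1)} used
#' by the element-continuity equation. Each row of `D` sums to 0 (the
#' Lagrange basis is a partition of unity) and \eqn{\ell_k(\tau_j) =
#' \delta_{kj}} by construction.
#'
#' @param taus distinct interpolation abscissas.
#' @return list with `D` ((K+1) x (K+1) matrix, rows indexed by evaluation
#'   node) and `lend` (vector of \eqn{\ell_k(1)}).
#' @export
lagrange_derivative_table <- function(taus) {
  n <- length(taus)
  if (anyDuplicated(taus)) stop_mhode("duplicate abscissa", "argument")
  # barycentric weights
  w <- vapply(seq_len(n), function(k) 1 / prod(taus[k] - taus[-k]), numeric(1))
  D <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j != k) D[j, k] <- (w[k] / w[j]) / (taus[j] - taus[k])
    }
    D[j, j] <- -sum(D[j, -j])
  }
  lend <- vapply(seq_len(n), function(k) {
    prod((1 - taus[-k]) / (taus[k] - taus[-k]))
  }, numeric(1))
  list(D = D, lend = lend)
}

#' Build a collocation grid over a time interval
#'
#' Uniform finite elements with K Radau points each; element start points
#' (\eqn{\tau_0 = 0}) are interpolation nodes but not residual nodes. The
#' grid holds the node times \eqn{t_{ij} = t_{i-1} + \tau_j h_i} and the
#' Lagrange differentiation table shared by all elements.
#'
#' @param t_start,t_end interval bounds (`t_start < t_end`).
#' @param N number of finite elements (>= 1).
#' @param K collocation points per element.
#' @return an object of class `mhode_grid` with fields `boundaries`, `h`,
#'   `K`, `N`, `taus` (length K+1, starting at 0), `D`, `lend`, `times`
#'   (N x (K+1) matrix of node times) and `node_times` (the N*K+1 distinct
#'   times).
#' @export
build_grid <- function(t_start, t_end, N, K = 3) {
  if (!(t_start < t_end)) stop_mhode("t_start must be < t_end", "argument")
  if (N < 1) stop_mhode("N must be >= 1", "argument")
  taus <- c(0, radau_points(K))
  tab <- lagrange_derivative_table(taus)
  boundaries <- seq(t_start, t_end, length.out = N + 1)
  h <- diff(boundaries)
  times <- outer(boundaries[-(N + 1)], rep(1, K + 1)) + outer(h, taus)
  node_times <- c(times[, 1], times[, K + 1][N])
  node_times <- sort(unique(as.vector(times)))
  structure(list(boundaries = boundaries, h = h, N = N, K = K, taus = taus,
                 D = tab$D, lend = tab$lend, times = times,
                 node_times = node_times),
            class = "mhode_grid")
}

#' @export
print.mhode_grid <- function(x, ...) {
  cat(sprintf("<mhode_grid> [%g, %g], N=%d elements, K=%d Radau points (%d nodes)\n",
              x$boundaries[1], x$boundaries[length(x$boundaries)], x$N, x$K,
              length(x$node_times)))
  invisible(x)
}

#' Collocation residuals for given nodal states and right-hand sides
#'
#' Computes the derivative-match residuals
#' \eqn{r_{ij} = (1/h_i) \sum_k X_{ik} D[j,k] - F_{ij}} at the K residual
#' nodes of each element, and the continuity residuals
#' \eqn{x_{i+1,0} - \sum_k \ell_k(1) x_{ik}}. All residuals vanish iff `X`
#' solves the collocation equations for `F`.
#'
#' @param grid a [build_grid()] object.
#' @param X numeric array `[N, K+1, n_x]` of states at all nodes.
#' @param F numeric array `[N, K, n_x]` of right-hand-side values at the
#'   residual nodes (j = 1..K).
#' @return list with `derivative` (`[N, K, n_x]` array) and `continuity`
#'   (`[N-1, n_x]` matrix, zero-row matrix when N = 1).
#' @export
collocation_residuals <- function(grid, X, F) {
  dX <- dim(X); dF <- dim(F)
  if (length(dX) != 3 || dX[1] != grid$N || dX[2] != grid$K + 1) {
    stop_mhode("X must be [N, K+1, n_x]", "argument")
  }
  if (length(dF) != 3 || dF[1] != grid$N || dF[2] != grid$K || dF[3] != dX[3]) {
    stop_mhode("F must be [N, K, n_x]", "argument")
  }
  nx <- dX[3]
  Dr <- grid$D[2:(grid$K + 1), , drop = FALSE]   # rows at residual nodes
  deriv <- array(0, dim = c(grid$N, grid$K, nx))
  for (s in seq_len(nx)) {
    deriv[, , s] <- (X[, , s, drop = FALSE][, , 1] %*% t(Dr)) / grid$h - F[, , s]
  }
  cont <- matrix(0, max(grid$N - 1, 0), nx)
  if (grid$N > 1) {
    for (s in seq_len(nx)) {
      interp_end <- X[, , s, drop = FALSE][, , 1] %*% grid$lend
      cont[, s] <- X[2:grid$N, 1, s] - interp_end[1:(grid$N - 1)]
    }
  }
  list(derivative = deriv, continuity = cont)
}
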