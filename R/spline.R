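#' Not-a-knot cubic spline interpolation
#'
#' Interpolates `(x, y)` with a cubic spline using not-a-knot end conditions
#' (the third derivative is continuous across the second and the
#' second-to-last knot). This dialect reproduces any cubic polynomial exactly,
#' which makes it a safe choice for transferring smooth state trajectories
#' onto collocation nodes without boundary flattening.
#'
#' @param x strictly increasing knot locations (length >= 4).
#' @param y values at the knots.
#' @param xq query locations; must lie within `[min(x), max(x)]`
#'   (no extrapolation).
#' @return numeric vector of interpolated values at `xq`.
#' @export
spline_notaknot <- function(x, y, xq) {
  n <- length(x)
  if (n < 4) {
    stop_mhode("not-a-knot cubic spline needs at least 4 knots", "insufficient_data")
  }
  if (length(y) != n) stop_mhode("x and y lengths differ", "argument")
  if (any(diff(x) <= 0)) stop_mhode("knots must be strictly increasing", "argument")
  rng <- range(x)
  tol <- 1e-10 * max(1, abs(rng))
  if (any(xq < rng[1] - tol) || any(xq > rng[2] + tol)) {
    stop_mhode("query points outside the sampled range (no extrapolation)", "extrapolation")
  }
  h <- diff(x)
  # Solve for the second derivatives M_i (the "moments") of the spline.
  # Interior rows: continuity of the first derivative; end rows: not-a-knot.
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  rhs <- numeric(n)
  for (i in 2:(n - 1)) {
    rows <- c(rows, i, i, i)
    cols <- c(cols, i - 1L, i, i + 1L)
    vals <- c(vals, h[i - 1] / 6, (h[i - 1] + h[i]) / 3, h[i] / 6)
    rhs[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  rows <- c(rows, 1L, 1L, 1L)
  cols <- c(cols, 1L, 2L, 3L)
  vals <- c(vals, h[2], -(h[1] + h[2]), h[1])
  rows <- c(rows, n, n, n)
  cols <- c(cols, n - 2L, n - 1L, n)
  vals <- c(vals, h[n - 1], -(h[n - 2] + h[n - 1]), h[n - 2])
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
  M <- as.numeric(Matrix::solve(A, rhs))

  xq_cl <- pmin(pmax(xq, rng[1]), rng[2])
  idx <- findInterval(xq_cl, x, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), n - 1L)
  hi <- h[idx]
  a <- x[idx + 1] - xq_cl
  b <- xq_cl - x[idx]
  M[idx] * a^3 / (6 * hi) + M[idx + 1] * b^3 / (6 * hi) +
    (y[idx] / hi - M[idx] * hi / 6) * a +
    (y[idx + 1] / hi - M[idx + 1] * hi / 6) * b
}
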