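#' Adaptive Savitzky-Golay smoothing
#'
#' Smooths each state column with a Savitzky-Golay filter, growing the window
#' until the estimated noise component stabilizes. The noise estimate is the
#' standard deviation of (raw - smoothed); the window grows by `dw` (kept
#' odd) until the relative change of that estimate falls below `tol` or the
#' window exceeds `ceiling(m / 4)` samples. Inputs are left untouched and
#' the time grid is never altered.
#'
#' @param ts a [timeseries()] object.
#' @param polyorder local polynomial order (default 3; signals that are
#'   polynomials of degree <= polyorder pass through unchanged).
#' @param tol relative tolerance on the change of the noise estimate.
#' @param w0 initial window length (odd, > polyorder).
#' @param dw window increment per trial (made even internally so windows
#'   stay odd).
#' @return list with `ts` (smoothed series, `smoothed` flag set) and
#'   `report` (tibble: state, window, polyorder, noise_sd, iterations,
#'   noise_trace list-column).
#' @export
smooth_adaptive <- function(ts, polyorder = 3, tol = 0.01, w0 = 5, dw = 2) {
  m <- nrow(ts)
  if (w0 %% 2 == 0) w0 <- w0 + 1
  if (dw %% 2 == 1) dw <- dw + 1
  if (w0 <= polyorder) stop_mhode("initial window must exceed polyorder", "argument")
  if (m <= w0) stop_mhode("series shorter than the initial smoothing window", "insufficient_data")
  w_cap <- max(w0, ceiling(m / 4))
  X <- ts_states(ts)
  out <- X
  rep_rows <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    w <- w0
    trace <- numeric(0)
    ws <- integer(0)
    sm_acc <- NULL
    iterations <- 0L
    plateau <- FALSE
    repeat {
      iterations <- iterations + 1L
      sm <- signal::sgolayfilt(x, p = polyorder, n = w)
      sigma <- stats::sd(x - sm)
      trace <- c(trace, sigma)
      ws <- c(ws, w)
      if (iterations == 1L && sigma < 1e-3 * max(sqrt(mean(x^2)), 1e-300)) {
        # residual at the minimal window is a small fraction of the signal:
        # effectively noiseless data (the minimal-window residual of truly
        # noisy data is close to the noise sd), so any further smoothing
        # only distorts -- accept the minimal window
        sm_acc <- sm; plateau <- TRUE; break
      }
      if (length(trace) >= 2) {
        prev <- trace[length(trace) - 1]
        rel <- abs(sigma - prev) / max(prev, 1e-12)
        # A genuine plateau must also be flat on the doubling scale:
        # smoothing distortion of a noiseless signal grows as a power of w,
        # which makes consecutive increments small even though the estimate
        # keeps climbing.
        half <- which(ws <= w / 2)
        flat_scale <- length(half) == 0 ||
          sigma < 1.5 * trace[half[length(half)]]
        if (rel < tol && flat_scale) { sm_acc <- sm; plateau <- TRUE; break }
      }
      if (w + dw > w_cap) { sm_acc <- sm; break }
      w <- w + dw
    }
    if (!plateau) {
      # No plateau in the noise estimate: the residual kept growing with
      # the window, i.e. it is smoothing distortion, not noise (essentially
      # noiseless signal). Fall back to the minimal window.
      w <- w0
      sm_acc <- signal::sgolayfilt(x, p = polyorder, n = w)
      trace <- c(trace, stats::sd(x - sm_acc))
    }
    out[, j] <- sm_acc
    rep_rows[[j]] <- tibble::tibble(
      state = state_names(ts)[j], window = w, polyorder = polyorder,
      noise_sd = trace[length(trace)], iterations = iterations,
      noise_trace = list(trace)
    )
  }
  list(ts = ts_replace_states(ts, out, smoothed = TRUE),
       report = dplyr::bind_rows(rep_rows))
}

#' Central-difference derivative estimates
#'
#' Interior-point central differences
#' \eqn{(x(t_{k+1}) - x(t_{k-1})) / (t_{k+1} - t_{k-1})}; the two endpoint
#' samples are dropped. Exact for affine and (on a uniform grid) quadratic
#' signals.
#'
#' @param ts a [timeseries()] object with at least 3 samples.
#' @return tibble with the interior times and one derivative column per
#'   state (same names as the state columns).
#' @export
estimate_derivatives_central <- function(ts) {
  m <- nrow(ts)
  if (m < 3) stop_mhode("central differences need at least 3 samples", "insufficient_data")
  tv <- ts_times(ts)
  X <- ts_states(ts)
  num <- X[3:m, , drop = FALSE] - X[1:(m - 2), , drop = FALSE]
  den <- tv[3:m] - tv[1:(m - 2)]
  D <- sweep(num, 1, den, "/")
  out <- tibble::as_tibble(as.data.frame(D))
  names(out) <- state_names(ts)
  dplyr::bind_cols(tibble::tibble(t = tv[2:(m - 1)]), out)
}

# ---- stationarity ---------------------------------------------------------

# Augmented Dickey-Fuller unit-root test with intercept. Returns the tau
# statistic for the lagged level in
#   diff(y)_t = a + b * y_{t-1} + sum_i g_i diff(y)_{t-i} + e_t.
adf_statistic <- function(y, lags = NULL) {
  n <- length(y)
  lags <- lags %||% max(1L, trunc((n - 1)^(1/3)))
  dy <- diff(y)
  nd <- length(dy)
  yl <- y[(lags + 1):(n - 1)]
  ddep <- dy[(lags + 1):nd]
  Z <- cbind(1, yl)
  for (i in seq_len(lags)) Z <- cbind(Z, dy[(lags + 1 - i):(nd - i)])
  fit <- stats::lm.fit(Z, ddep)
  res <- fit$residuals
  dof <- max(length(ddep) - ncol(Z), 1)
  s2 <- sum(res^2) / dof
  XtXinv <- tryCatch(chol2inv(chol(crossprod(Z))), error = function(e) NULL)
  if (is.null(XtXinv)) {  # collinear lag design (e.g. noiseless signals)
    sv <- svd(Z)
    dinv2 <- ifelse(sv$d > 1e-10 * sv$d[1], 1 / sv$d^2, 0)
    XtXinv <- sv$v %*% (dinv2 * t(sv$v))
  }
  se_b <- sqrt(s2 * XtXinv[2, 2])
  unname(fit$coefficients[2] / se_b)
}

# Asymptotic critical values of the tau_mu (intercept) Dickey-Fuller
# distribution; interpolated linearly in significance level.
adf_critical <- function(alpha) {
  lv <- c(0.01, 0.025, 0.05, 0.10)
  cv <- c(-3.43, -3.12, -2.86, -2.57)
  stats::approx(lv, cv, xout = min(max(alpha, lv[1]), lv[4]))$y
}

#' Enforce stationarity by differencing
#'
#' Applies the augmented Dickey-Fuller unit-root test (intercept variant,
#' asymptotic critical values) and differences the series until the null of
#' a unit root is rejected at level `alpha`, up to `d_max` times.
#'
#' @param series numeric vector (length >= 20 for a meaningful test).
#' @param alpha significance level.
#' @param d_max maximum differencing order.
#' @return list with `series` (processed), `d` (differencing order applied),
#'   `statistic` (last ADF tau), `zero_variance` (degenerate constant series
#'   flag) and `failed` (`TRUE` if still non-stationary at `d_max`).
#' @export
enforce_stationarity <- function(series, alpha = 0.05, d_max = 2) {
  if (length(series) < 20) stop_mhode("need at least 20 observations", "insufficient_data")
  if (stats::sd(series) < 1e-12) {
    return(list(series = series, d = 0L, statistic = NA_real_,
                zero_variance = TRUE, failed = FALSE))
  }
  cv <- adf_critical(alpha)
  y <- series
  d <- 0L
  repeat {
    stat <- adf_statistic(y)
    if (is.finite(stat) && stat < cv) {
      return(list(series = y, d = d, statistic = stat,
                  zero_variance = FALSE, failed = FALSE))
    }
    if (d >= d_max) {
      return(list(series = y, d = d, statistic = stat,
                  zero_variance = FALSE, failed = TRUE))
    }
    y <- diff(y)
    d <- d + 1L
  }
}

# ---- Granger screening ----------------------------------------------------

#' Granger-causality screening of the dictionary
#'
#' For each (function i, state j) pair, tests whether the lagged series
#' \eqn{\theta_i(\tilde X)} helps predict \eqn{\tilde X_j} (F-test at lag
#' `maxlag`), after differencing both series to stationarity. Pairs whose
#' p-value is >= `alpha` are marked for removal. Constant-valued regressors
#' are exempt (the test is undefined at zero variance), as are pairs whose
#' regression is degenerate (conservative: keep, warn).
#'
#' @param lib a `mhode_library`.
#' @param ts_smoothed smoothed [timeseries()].
#' @param maxlag Granger lag order.
#' @param alpha significance level for retention.
#' @param d_alpha,d_max stationarity-test level and maximum differencing.
#' @return list with `pvals` (n_theta x n_x matrix), `mask` (retention),
#'   and `stationarity` (per-state tibble).
#' @export
granger_screen <- function(lib, ts_smoothed, maxlag = 1, alpha = 0.05,
                           d_alpha = 0.05, d_max = 2) {
  X <- ts_states(ts_smoothed)
  U <- ts_inputs(ts_smoothed)
  Theta <- evaluate_matrix(lib, X, U)
  nf <- n_functions(lib)
  nx <- ncol(X)
  pvals <- matrix(NA_real_, nf, nx, dimnames = list(function_names(lib), state_names(ts_smoothed)))
  mask <- matrix(TRUE, nf, nx, dimnames = dimnames(pvals))
  st_rows <- vector("list", nx)
  for (j in seq_len(nx)) {
    stj <- enforce_stationarity(X[, j], alpha = d_alpha, d_max = d_max)
    st_rows[[j]] <- tibble::tibble(state = state_names(ts_smoothed)[j], d = stj$d,
                                   statistic = stj$statistic, failed = stj$failed)
    if (stj$failed) next  # screening skipped for this state; everything kept
    yj <- stj$series
    for (i in seq_len(nf)) {
      th <- Theta[, i]
      if (stats::sd(th) < 1e-12) next  # constant regressor: exempt, retained
      sti <- enforce_stationarity(th, alpha = d_alpha, d_max = d_max)
      if (sti$failed) next  # conservative: keep
      xi <- sti$series
      len <- min(length(yj), length(xi))
      y2 <- yj[(length(yj) - len + 1):length(yj)]
      x2 <- xi[(length(xi) - len + 1):length(xi)]
      p <- tryCatch({
        gt <- lmtest::grangertest(x = x2, y = y2, order = maxlag)
        gt[["Pr(>F)"]][2]
      }, error = function(e) NA_real_)
      if (is.na(p)) {
        warn_mhode(paste0("degenerate Granger regression for '", function_names(lib)[i],
                          "' vs state ", j, "; pair retained"), "granger")
        next
      }
      pvals[i, j] <- p
      if (p >= alpha) mask[i, j] <- FALSE
    }
  }
  list(pvals = pvals, mask = mask, stationarity = dplyr::bind_rows(st_rows))
}

# ---- OLS initialization ---------------------------------------------------

# Sequentially thresholded least squares over a grid of relative
# thresholds, one variable eliminated per refit, best fixpoint chosen by
# BIC. `Ds` must be column-scaled. Returns the coefficient vector in the
# scaled basis. Used only to refine the moving-horizon warm-start anchor;
# it makes no binding structure decision.
stls_anchor <- function(Ds, y,
                        thresholds = c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4),
                        pool = rep(TRUE, ncol(Ds))) {
  n <- length(y)
  best <- NULL; best_bic <- Inf
  ls_fit <- function(cols) {
    tryCatch(qr.solve(Ds[, cols, drop = FALSE], y),
             error = function(e) ols_minnorm(Ds[, cols, drop = FALSE], y)$coef)
  }
  if (!any(pool)) pool <- rep(TRUE, ncol(Ds))
  for (thr in thresholds) {
    keep <- pool; b <- rep(0, ncol(Ds))
    repeat {
      b[] <- 0
      b[keep] <- ls_fit(keep)
      cand <- which(keep & abs(b) < thr * max(abs(b)))
      if (length(cand) == 0 || sum(keep) <= 1) break
      keep[cand[which.min(abs(b)[cand])]] <- FALSE
    }
    rss <- sum((y - Ds %*% b)^2)
    bic <- n * log(max(rss, 1e-300) / n) + sum(keep) * log(n)
    if (bic < best_bic) { best_bic <- bic; best <- b }
  }
  list(coef = best, bic = best_bic)
}

# Columns reproducible (R^2 above `r2_tol`) from earlier -- i.e. simpler --
# columns over the observed data are "shadowed": over the sampled state
# range they are statistically indistinguishable from a combination of
# lower-order terms (e.g. sin(x) vs x - x^3/6 on a narrow range), so the
# sparse warm-start anchor prefers the simpler representation. Shadowed
# columns remain free variables in every window problem; only the
# coefficient-of-variation rule removes them from the model.
shadowed_columns <- function(Ds, r2_tol = 0.9999) {
  k <- ncol(Ds)
  shadowed <- logical(k)
  if (k < 2) return(shadowed)
  # compare *variations*: a column is shadowed only if its centered values
  # are reproducible from the centered simpler columns (otherwise any
  # column with small relative variation -- a nearly constant input, say --
  # would be absorbed by the constant term even though its variation
  # carries independent signal)
  Dc <- scale(Ds, center = TRUE, scale = FALSE)
  vq <- colSums(Dc^2)
  for (q in k:2) {
    if (vq[q] < 1e-12 * nrow(Ds)) next   # constant column: exempt
    base <- which(!shadowed[seq_len(q - 1)] & vq[seq_len(q - 1)] > 1e-12 * nrow(Ds))
    if (length(base) == 0) next
    fit <- tryCatch(stats::lm.fit(Dc[, base, drop = FALSE], Dc[, q]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    r2 <- 1 - sum(fit$residuals^2) / vq[q]
    if (is.finite(r2) && r2 > r2_tol) shadowed[q] <- TRUE
  }
  shadowed
}

# Minimum-norm least squares via truncated SVD. Monomial dictionaries
# evaluated along a single trajectory (worse: a closed orbit) are severely
# ill-conditioned; directions with singular values below rtol * s_max are
# truncated so the returned coefficients stay at a physical scale instead of
# exploding along near-null directions. Standard errors and p-values use
# the full pseudo-inverse covariance (huge along truncated directions,
# which correctly translates into loose bounds).
ols_minnorm <- function(X, y, rtol = 1e-6) {
  # column scaling first: raw monomial columns span many orders of
  # magnitude, and the minimum-norm criterion is only meaningful on a
  # fair (unit-RMS) scale.
  s <- sqrt(colMeans(X^2))
  s[s < 1e-300] <- 1
  Xs <- sweep(X, 2, s, "/")
  sv <- svd(Xs)
  pos <- sv$d > rtol * sv$d[1]
  dinv <- ifelse(pos, 1 / sv$d, 0)
  beta_s <- sv$v %*% (dinv * crossprod(sv$u, y))
  res <- y - Xs %*% beta_s
  dof <- max(length(y) - sum(pos), 1)
  s2 <- sum(res^2) / dof
  # covariance along kept directions; truncated directions get the largest
  # kept variance inflated, signalling "unidentified"
  var_dir <- ifelse(pos, dinv^2, max(dinv^2) * 1e4)
  se_s <- sqrt(s2 * rowSums(sweep(sv$v^2, 2, var_dir, "*")))
  tstat <- as.numeric(beta_s) / pmax(se_s, 1e-300)
  pval <- 2 * stats::pt(-abs(tstat), df = dof)
  list(coef = as.numeric(beta_s) / s, se = se_s / s, pval = pval,
       truncated = any(!pos), col_scale = s)
}

#' Ordinary-least-squares initialization and coefficient bounds
#'
#' Regresses central-difference derivative estimates on the active dictionary
#' columns (parametric terms evaluated at their initial parameter values),
#' per state. The point estimates seed the first optimization window and the
#' widened confidence intervals become coefficient bounds
#' `[est - z * se * s_widen, est + z * se * s_widen]`. Because noise can bias
#' these regressions, bounds are deliberately loose and, unless
#' `include_zero = FALSE`, always include 0.
#'
#' @param lib a `mhode_library` (mask already reflecting any Granger
#'   screening).
#' @param ts_smoothed smoothed [timeseries()].
#' @param derivs derivative tibble from [estimate_derivatives_central()]
#'   (computed if omitted).
#' @param conf confidence level for the intervals.
#' @param s_widen multiplicative widening factor on the half-width.
#' @param include_zero force bounds to include zero (default).
#' @return an object of class `mhode_screening`: matrices `xi_ols`, `se`,
#'   `pval`, `lower`, `upper` (n_theta x n_x; NA at inactive pairs), the
#'   retention `mask`, and `rank_deficient` flags per state.
#' @export
ols_initialize <- function(lib, ts_smoothed, derivs = NULL, conf = 0.999,
                           s_widen = 5, include_zero = TRUE) {
  if (is.null(derivs)) derivs <- estimate_derivatives_central(ts_smoothed)
  X <- ts_states(ts_smoothed)
  U <- ts_inputs(ts_smoothed)
  m <- nrow(X)
  interior <- 2:(m - 1)
  Theta <- evaluate_matrix(lib, X[interior, , drop = FALSE],
                           U[interior, , drop = FALSE])
  nf <- n_functions(lib)
  nx <- length(lib$state_names)
  dm <- as.matrix(derivs[state_names(ts_smoothed)])
  shape <- function() matrix(NA_real_, nf, nx, dimnames = list(function_names(lib), lib$state_names))
  est <- shape(); se <- shape(); pv <- shape(); lo <- shape(); up <- shape()
  rankdef <- logical(nx)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  for (j in seq_len(nx)) {
    act <- which(lib$active[, j])
    if (length(act) == 0) next
    D <- Theta[, act, drop = FALSE]
    # exact duplicate columns: drop all but the first, warn
    dup <- duplicated(t(round(D, 12)))
    if (any(dup)) {
      warn_mhode("exactly duplicated dictionary columns dropped for OLS", "rank_deficiency")
      rankdef[j] <- TRUE
    }
    keep <- act[!dup]
    fit <- ols_minnorm(Theta[, keep, drop = FALSE], dm[, j])
    if (fit$truncated) rankdef[j] <- TRUE
    est_j <- fit$coef
    # Standard errors from the full (untruncated) covariance, floored:
    # near-collinear dictionary columns would otherwise produce degenerate
    # (zero-width at zero noise, or absurdly wide) bounds. The floor keeps
    # bounds deliberately loose relative to the coefficient scale.
    se_j <- pmax(fit$se, 0.05 * (1 + abs(est_j)))
    est[keep, j] <- est_j
    se[keep, j] <- se_j
    pv[keep, j] <- fit$pval
    lo[keep, j] <- est_j - z * se_j * s_widen
    up[keep, j] <- est_j + z * se_j * s_widen
    if (any(dup)) {  # duplicates get a zero estimate with wide bounds
      big <- max(1, 10 * max(abs(est_j)))
      for (d_i in act[dup]) {
        est[d_i, j] <- 0; se[d_i, j] <- big
        lo[d_i, j] <- -z * big * s_widen; up[d_i, j] <- z * big * s_widen
      }
    }
    if (include_zero) {
      lo[, j] <- pmin(lo[, j], 0)
      up[, j] <- pmax(up[, j], 0)
    }
  }
  # Sparse-refined anchor: sequentially thresholded least squares on the
  # scaled dictionary. This refines the warm start only -- every active
  # pair remains a free variable in the window problems and the
  # coefficient-of-variation thresholding makes all structure decisions --
  # but anchoring the window chain near a parsimonious solution keeps the
  # identifiable coefficients' window estimates stable, which is what the
  # variance-based pruning assumes.
  anchor_pass <- function(Theta_eval) {
    xi <- est
    xi[is.na(xi)] <- 0
    total_bic <- 0
    for (j in seq_len(nx)) {
      act <- which(lib$active[, j])
      if (length(act) < 2) next
      D <- Theta_eval[, act, drop = FALSE]
      cs <- sqrt(colMeans(D^2)); cs[cs < 1e-300] <- 1
      Ds <- sweep(D, 2, cs, "/")
      res <- stls_anchor(Ds, dm[, j], pool = !shadowed_columns(Ds))
      xi[act, j] <- res$coef / cs
      total_bic <- total_bic + res$bic
    }
    list(xi = xi, bic = total_bic)
  }

  ptab <- lib_param_table(lib)
  c_init <- stats::setNames(ptab$init, ptab$name)
  if (nrow(ptab) == 0) {
    xi_init <- anchor_pass(Theta)$xi
  } else {
    # profile the nonlinear parameters: the dictionary evaluated at a wrong
    # parameter value has the wrong column shape and the sparse anchor then
    # discards the true term; pick the grid value with the best total BIC
    grids <- lapply(seq_len(nrow(ptab)), function(i) {
      seq(ptab$lower[i], ptab$upper[i], length.out = 9)
    })
    combos <- expand.grid(grids)
    names(combos) <- ptab$name
    best <- NULL
    for (r in seq_len(nrow(combos))) {
      cv <- as.list(combos[r, , drop = FALSE])
      Th_r <- evaluate_matrix(lib, X[interior, , drop = FALSE],
                              U[interior, , drop = FALSE], c_values = cv)
      cand <- anchor_pass(Th_r)
      if (is.null(best) || cand$bic < best$bic) {
        best <- cand
        c_init <- stats::setNames(unlist(cv), ptab$name)
      }
    }
    xi_init <- best$xi
  }
  structure(list(xi_ols = est, xi_init = xi_init, c_init = c_init,
                 se = se, pval = pv,
                 lower = lo, upper = up,
                 mask = lib$active, rank_deficient = rankdef,
                 conf = conf, s_widen = s_widen),
            class = "mhode_screening")
}

#' @export
print.mhode_screening <- function(x, ...) {
  cat(sprintf("<mhode_screening> %d/%d (function, state) pairs retained\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' One-call preprocessing and screening pipeline
#'
#' Smooths the series ([smooth_adaptive()]), optionally applies
#' Granger-causality screening ([granger_screen()]) to shrink the dictionary,
#' and computes OLS initial estimates and bounds ([ols_initialize()]).
#' Screening is advisory: with `use_granger = FALSE` (or when it fails) the
#' moving-horizon stage still operates on the full dictionary.
#'
#' @param ts raw [timeseries()].
#' @param lib a `mhode_library`.
#' @param use_granger apply Granger screening?
#' @param use_shadow apply the identifiability (shadowing) screen: drop
#'   basis functions whose values over the observed data are numerically
#'   indistinguishable from a combination of simpler terms (see Details in
#'   the source; protected terms are never dropped)?
#' @param alpha Granger retention level.
#' @param maxlag Granger lag order.
#' @param conf,s_widen bound-construction knobs (see [ols_initialize()]).
#' @param ... passed to [smooth_adaptive()].
#' @return list with `ts` (smoothed), `lib` (mask intersected with the
#'   screen), `screening` (`mhode_screening`), `smoothing` (report), and
#'   `granger` (raw screen, or NULL).
#' @export
preprocess <- function(ts, lib, use_granger = TRUE, use_shadow = TRUE,
                       alpha = 0.05, maxlag = 1,
                       conf = 0.999, s_widen = 5, ...) {
  sm <- smooth_adaptive(ts, ...)
  gr <- NULL
  if (use_granger) {
    orig <- lib$active
    gr <- granger_screen(lib, sm$ts, maxlag = maxlag, alpha = alpha)
    lib$active <- lib$active & gr$mask
    # never leave a state equation empty-handed
    for (j in seq_len(ncol(lib$active))) {
      if (!any(lib$active[, j])) lib$active[, j] <- orig[, j]
    }
  }
  sc <- ols_initialize(lib, sm$ts, conf = conf, s_widen = s_widen)
  shadow <- NULL
  if (use_shadow) {
    # Identifiability screen: a basis function whose centered values over
    # the observed data are reproducible (R^2 > 0.9999) from simpler
    # (earlier-ordered) functions is indistinguishable from that
    # combination on these data -- no estimator could tell them apart, and
    # keeping both creates a degenerate direction that variance-based
    # thresholding cannot resolve. The simpler representation is kept
    # (e.g. sin(x) over a narrow state range collapses onto x - x^3/6).
    # Protected (constant/linear) functions are never shadowed.
    Th_all <- evaluate_matrix(lib, ts_states(sm$ts), ts_inputs(sm$ts),
                              c_values = as.list(sc$c_init))
    cs <- sqrt(colMeans(Th_all^2)); cs[cs < 1e-300] <- 1
    shadow <- shadowed_columns(sweep(Th_all, 2, cs, "/"))
    prot <- vapply(lib$functions, `[[`, logical(1), "protected")
    shadow <- shadow & !prot
    if (any(shadow)) lib$active[shadow, ] <- FALSE
  }
  list(ts = sm$ts, lib = lib, screening = sc, smoothing = sm$report,
       granger = gr, shadowed = shadow)
}

#' Serialize a screening report to JSON
#' @param screening a `mhode_screening`.
#' @param path file path.
#' @export
screening_to_json <- function(screening, path) {
  jsonlite::write_json(lapply(screening[c("xi_ols", "se", "pval", "lower", "upper", "mask")],
                              function(m) as.data.frame(m)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
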