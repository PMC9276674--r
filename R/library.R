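#' Candidate basis-function dictionaries
#'
#' A `mhode_library` is an ordered dictionary of candidate symbolic terms
#' \eqn{\theta_i(x, u; c)} together with an activity mask over
#' (function, state) pairs: discovery means deciding which pairs carry a
#' nonzero coefficient in \eqn{\dot x = \Xi^T \Theta(x, u, c)^T}. Terms may
#' carry nonlinear parameters `c` with bounds (e.g. an Arrhenius activation
#' energy inside an exponential), which are estimated jointly with the
#' coefficients.
#'
#' @param state_names,input_names symbol names the expressions may reference.
#' @return an empty `mhode_library`; add terms with
#'   [build_polynomial_terms()], [add_elementary_terms()] or
#'   [add_custom_term()].
#' @export
basis_library <- function(state_names, input_names = character()) {
  structure(
    list(state_names = state_names, input_names = input_names %||% character(),
         functions = list(),
         active = matrix(logical(0), nrow = 0, ncol = length(state_names),
                         dimnames = list(NULL, state_names))),
    class = "mhode_library"
  )
}

#' @export
print.mhode_library <- function(x, ...) {
  cat(sprintf("<mhode_library> %d function(s) over states [%s]%s; %d active pair(s)\n",
              n_functions(x), paste(x$state_names, collapse = ", "),
              if (length(x$input_names)) paste0(" inputs [", paste(x$input_names, collapse = ", "), "]") else "",
              sum(x$active)))
  invisible(x)
}

#' @rdname basis_library
#' @param lib a `mhode_library`.
#' @export
n_functions <- function(lib) length(lib$functions)

#' @rdname basis_library
#' @export
function_names <- function(lib) vapply(lib$functions, `[[`, character(1), "name")

#' @rdname basis_library
#' @export
active_mask <- function(lib) lib$active

# ---- internal construction ------------------------------------------------

# A basis function stores its expression plus pre-differentiated partials
# with respect to every state symbol and every nonlinear parameter, so the
# optimizer can evaluate analytic Jacobians.
new_basis_function <- function(name, expr_text, lib, params = NULL, protected = FALSE) {
  params <- params %||% tibble::tibble(name = character(), lower = numeric(),
                                       upper = numeric(), init = numeric())
  expr <- tryCatch(str2lang(expr_text),
                   error = function(e) stop_mhode(
                     paste0("cannot parse expression '", expr_text, "': ", conditionMessage(e)),
                     "expression"))
  allowed <- c(lib$state_names, lib$input_names, params$name)
  used <- all.vars(expr)
  bad <- setdiff(used, allowed)
  if (length(bad) > 0) {
    stop_mhode(paste0("expression '", expr_text, "' references undeclared symbols: ",
                      paste(bad, collapse = ", ")), "argument")
  }
  if (nrow(params) > 0) {
    if (any(params$lower > params$upper)) {
      stop_mhode("parameter bounds must satisfy lower <= upper", "argument")
    }
    if (any(params$init < params$lower | params$init > params$upper)) {
      stop_mhode("parameter initial value must lie within [lower, upper]", "argument")
    }
  }
  dx <- lapply(lib$state_names, function(s) stats::D(expr, s))
  names(dx) <- lib$state_names
  dc <- lapply(params$name, function(p) stats::D(expr, p))
  names(dc) <- params$name
  list(name = name, text = expr_text, expr = expr, params = params,
       protected = isTRUE(protected), dx = dx, dc = dc)
}

lib_append <- function(lib, bf) {
  if (bf$name %in% function_names(lib)) {
    stop_mhode(paste0("basis function '", bf$name, "' already in the library"), "library")
  }
  dup_par <- intersect(bf$params$name, lib_param_table(lib)$name)
  if (length(dup_par) > 0) {
    stop_mhode(paste0("parameter name(s) already used: ", paste(dup_par, collapse = ", ")), "library")
  }
  lib$functions <- c(lib$functions, list(bf))
  lib$active <- rbind(lib$active, rep(TRUE, length(lib$state_names)))
  rownames(lib$active) <- function_names(lib)
  lib
}

# Table of all nonlinear parameters across the library.
lib_param_table <- function(lib) {
  tabs <- lapply(lib$functions, `[[`, "params")
  out <- do.call(rbind, c(list(tibble::tibble(name = character(), lower = numeric(),
                                              upper = numeric(), init = numeric())), tabs))
  tibble::as_tibble(out)
}

# ---- builders -------------------------------------------------------------

# Exponent vectors of all monomials of total degree <= d in graded
# lexicographic order (grade first, then lexicographic with the first
# variable dominant).
monomial_exponents <- function(n_vars, max_degree) {
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, ncol = 1))
    out <- NULL
    for (first in total:0) {
      rest <- compositions(total - first, parts - 1)
      out <- rbind(out, cbind(first, rest))
    }
    out
  }
  exps <- NULL
  for (d in 0:max_degree) exps <- rbind(exps, compositions(d, n_vars))
  unname(exps)
}

monomial_name <- function(expo, vars) {
  if (all(expo == 0)) return("1")
  pieces <- character(0)
  for (i in seq_along(vars)) {
    if (expo[i] == 1) pieces <- c(pieces, vars[i])
    if (expo[i] > 1) pieces <- c(pieces, paste0(vars[i], "^", expo[i]))
  }
  paste(pieces, collapse = "*")
}

#' Build all monomial terms up to a total degree
#'
#' Generates every monomial in the states (and, if `include_inputs = TRUE`,
#' the inputs) of total degree at most `max_degree`, including the constant
#' and all interaction terms, in deterministic graded-lexicographic order.
#' The constant and pure-linear terms are flagged protected: they are exempt
#' from coefficient-of-variation pruning during the initial grace period.
#'
#' @param n_x number of states (ignored if `state_names` given).
#' @param n_u number of inputs (ignored if `input_names` given).
#' @param max_degree maximum total degree (>= 0).
#' @param state_names,input_names symbol names; default `x1...`, `u1...`.
#' @param include_inputs if `TRUE` monomials range over states and inputs
#'   jointly; otherwise over states only (inputs stay available for custom
#'   terms).
#' @return a `mhode_library`.
#' @examples
#' lib <- build_polynomial_terms(n_x = 2, max_degree = 2)
#' function_names(lib)  # 1, x1, x2, x1^2, x1*x2, x2^2
#' @export
build_polynomial_terms <- function(n_x, n_u = 0, max_degree = 2,
                                   state_names = paste0("x", seq_len(n_x)),
                                   input_names = if (n_u > 0) paste0("u", seq_len(n_u)) else character(),
                                   include_inputs = FALSE) {
  if (max_degree < 0) stop_mhode("max_degree must be >= 0", "argument")
  lib <- basis_library(state_names, input_names)
  vars <- if (include_inputs) c(state_names, input_names) else state_names
  exps <- monomial_exponents(length(vars), max_degree)
  for (r in seq_len(nrow(exps))) {
    nm <- monomial_name(exps[r, ], vars)
    lib <- lib_append(lib, new_basis_function(nm, nm, lib,
                                              protected = sum(exps[r, ]) <= 1))
  }
  lib
}

#' Append elementary transcendental terms
#'
#' @param lib a `mhode_library`.
#' @param kinds subset of `c("sin", "cos", "exp")`.
#' @param targets symbols to transform (default: all states).
#' @return the enlarged library.
#' @export
add_elementary_terms <- function(lib, kinds = c("sin", "cos"), targets = lib$state_names) {
  kinds <- match.arg(kinds, c("sin", "cos", "exp"), several.ok = TRUE)
  bad <- setdiff(targets, c(lib$state_names, lib$input_names))
  if (length(bad) > 0) {
    stop_mhode(paste0("undeclared symbol(s): ", paste(bad, collapse = ", ")), "argument")
  }
  for (k in kinds) {
    for (tg in targets) {
      nm <- paste0(k, "(", tg, ")")
      lib <- lib_append(lib, new_basis_function(nm, nm, lib, protected = FALSE))
    }
  }
  lib
}

#' Append a custom (possibly nonlinearly parameterized) term
#'
#' @param lib a `mhode_library`.
#' @param name unique term name.
#' @param expression character expression over declared states, inputs and
#'   the parameters listed in `params`, e.g. `"x1*exp(-c1/x2)"`.
#' @param params optional data frame with columns `name`, `lower`, `upper`,
#'   `init` describing nonlinear parameters estimated jointly with the
#'   coefficients.
#' @param protected exempt from early thresholding?
#' @return the enlarged library.
#' @export
add_custom_term <- function(lib, name, expression, params = NULL, protected = FALSE) {
  if (!is.null(params)) params <- tibble::as_tibble(params)
  lib_append(lib, new_basis_function(name, expression, lib, params = params,
                                     protected = protected))
}

# ---- evaluation -----------------------------------------------------------

# Evaluate one expression in an environment of (vector-valued) symbols,
# recycling scalar results (e.g. the constant term) to m rows.
eval_expr_rows <- function(expr, env, m) {
  v <- eval(expr, envir = env)
  if (length(v) == 1) v <- rep(v, m)
  v
}

lib_eval_env <- function(lib, states, inputs, c_values) {
  env <- new.env(parent = baseenv())
  for (j in seq_along(lib$state_names)) assign(lib$state_names[j], states[, j], envir = env)
  if (length(lib$input_names) > 0) {
    for (j in seq_along(lib$input_names)) assign(lib$input_names[j], inputs[, j], envir = env)
  }
  ptab <- lib_param_table(lib)
  for (p in ptab$name) {
    if (!p %in% names(c_values)) stop_mhode(paste0("missing parameter value: ", p), "argument")
    assign(p, c_values[[p]], envir = env)
  }
  env
}

#' Evaluate the dictionary on a data matrix
#'
#' Entry `(k, i)` is \eqn{\theta_i} evaluated at row `k` of the data. The same
#' symbolic definitions serve statistical screening (numbers in, numbers out)
#' and optimization-model assembly (where states are decision variables).
#'
#' @param lib a `mhode_library`.
#' @param states m x n_x matrix of state values.
#' @param inputs m x n_u matrix of input values (may be omitted when the
#'   library declares no inputs).
#' @param c_values named list/vector of nonlinear-parameter values; defaults
#'   to each parameter's initial value. Values must lie within bounds.
#' @return m x n_theta numeric matrix with term names as column names.
#' @export
evaluate_matrix <- function(lib, states, inputs = NULL, c_values = NULL) {
  states <- as.matrix(states)
  m <- nrow(states)
  if (ncol(states) != length(lib$state_names)) {
    stop_mhode("state matrix has wrong number of columns", "argument")
  }
  if (is.null(inputs)) inputs <- matrix(numeric(0), nrow = m, ncol = 0)
  inputs <- as.matrix(inputs)
  ptab <- lib_param_table(lib)
  if (is.null(c_values)) c_values <- stats::setNames(as.list(ptab$init), ptab$name)
  for (i in seq_len(nrow(ptab))) {
    p <- ptab$name[i]
    if (p %in% names(c_values)) {
      v <- c_values[[p]]
      if (v < ptab$lower[i] - 1e-12 || v > ptab$upper[i] + 1e-12) {
        stop_mhode(paste0("parameter '", p, "' outside its bounds"), "argument")
      }
    }
  }
  env <- lib_eval_env(lib, states, inputs, c_values)
  out <- matrix(NA_real_, nrow = m, ncol = n_functions(lib),
                dimnames = list(NULL, function_names(lib)))
  for (i in seq_len(n_functions(lib))) {
    v <- eval_expr_rows(lib$functions[[i]]$expr, env, m)
    if (any(!is.finite(v))) {
      stop_mhode(paste0("non-finite evaluation of '", lib$functions[[i]]$name,
                        "' (first at row ", which(!is.finite(v))[1], ")"), "evaluation")
    }
    out[, i] <- v
  }
  out
}

# Evaluate values + partial derivatives of a subset of functions at node
# states; returns list(theta, dx = [m, nf, n_x], dc = [m, nf, n_c]).
# Used by the DNLP assembler; no finiteness check (the solver guards).
lib_eval_derivs <- function(lib, fidx, states, inputs, c_values) {
  m <- nrow(states)
  env <- lib_eval_env(lib, states, inputs, c_values)
  nf <- length(fidx)
  nx <- length(lib$state_names)
  ptab <- lib_param_table(lib)
  nc <- nrow(ptab)
  theta <- matrix(0, m, nf)
  dxa <- array(0, dim = c(m, nf, nx))
  dca <- if (nc > 0) array(0, dim = c(m, nf, nc)) else NULL
  if (nc > 0) cnames <- ptab$name
  for (q in seq_len(nf)) {
    bf <- lib$functions[[fidx[q]]]
    theta[, q] <- eval_expr_rows(bf$expr, env, m)
    for (j in seq_len(nx)) {
      dxa[, q, j] <- eval_expr_rows(bf$dx[[j]], env, m)
    }
    if (nc > 0 && nrow(bf$params) > 0) {
      for (p in bf$params$name) {
        dca[, q, match(p, cnames)] <- eval_expr_rows(bf$dc[[p]], env, m)
      }
    }
  }
  list(theta = theta, dx = dxa, dc = dca)
}

# ---- pruning --------------------------------------------------------------

#' Prune (function, state) pairs from the active mask
#'
#' Pruned pairs never re-enter: the active set is monotone non-increasing,
#' and pruning an already-inactive pair is a no-op. Functions inactive for
#' every state are excluded from future optimization problems but retained
#' in the record for reporting.
#'
#' @param lib a `mhode_library`.
#' @param drops data frame with integer columns `fn` (function index) and
#'   `state` (state index), or a 2-column matrix.
#' @return the library with the mask entries set `FALSE`.
#' @export
prune <- function(lib, drops) {
  if (is.matrix(drops)) drops <- data.frame(fn = drops[, 1], state = drops[, 2])
  if (nrow(drops) == 0) return(lib)
  if (any(drops$fn < 1 | drops$fn > n_functions(lib)) ||
      any(drops$state < 1 | drops$state > length(lib$state_names))) {
    stop_mhode("prune index out of range", "argument")
  }
  lib$active[cbind(drops$fn, drops$state)] <- FALSE
  lib
}

# Active (function, state) index pairs, in column-major (state-major) order.
active_pairs <- function(lib) {
  idx <- which(lib$active, arr.ind = TRUE)
  tibble::tibble(fn = as.integer(idx[, 1]), state = as.integer(idx[, 2]))
}

# ---- serialization --------------------------------------------------------

#' Serialize / restore a library as JSON
#'
#' @param lib a `mhode_library`.
#' @param path file path.
#' @return `library_from_json()` returns the restored `mhode_library`.
#' @export
library_to_json <- function(lib, path) {
  doc <- list(
    state_names = lib$state_names,
    input_names = lib$input_names,
    functions = lapply(lib$functions, function(bf) {
      list(name = bf$name, expression = bf$text, protected = bf$protected,
           params = as.list(bf$params))
    }),
    active = lib$active
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname library_to_json
#' @export
library_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- basis_library(doc$state_names, doc$input_names %||% character())
  fns <- doc$functions
  for (i in seq_len(nrow(fns))) {
    par <- fns$params[i, , drop = FALSE]
    params <- if (length(par$name[[1]]) > 0) {
      tibble::tibble(name = unlist(par$name), lower = unlist(par$lower),
                     upper = unlist(par$upper), init = unlist(par$init))
    } else NULL
    lib <- lib_append(lib, new_basis_function(fns$name[i], fns$expression[i], lib,
                                              params = params,
                                              protected = isTRUE(fns$protected[i])))
  }
  lib$active <- matrix(as.logical(doc$active), nrow = n_functions(lib),
                       dimnames = list(function_names(lib), lib$state_names))
  lib
}
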