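#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Structured error helper: every condition carries a package class so callers
# (and tests) can discriminate failure modes.
stop_mhode <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("mhode_error_", class), "mhode_error"), ...)
}

warn_mhode <- function(message, class = "generic") {
  rlang::warn(message, class = c(paste0("mhode_warning_", class), "mhode_warning"))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic per-replicate seed derivation used across benchmarks.
derive_seed <- function(master, level, replicate) {
  as.integer((as.numeric(master) * 100003 + level * 1009 + replicate * 7919) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
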