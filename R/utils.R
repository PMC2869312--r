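# Internal helpers: validation and seed plumbing.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(field, "must be a single positive finite number")
  invisible(x)
}

#' Derive a reproducible sub-seed
#'
#' Deterministically maps a master seed and an integer index to a new seed in
#' `[1, 2^31 - 2]`.  Used so that obstacle sampling, start-site draws and
#' per-phase walker streams all flow from one master seed.
#'
#' @param seed master seed (non-negative integer).
#' @param k stream index (non-negative integer).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + (as.double(k) + 1) * 16807
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
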