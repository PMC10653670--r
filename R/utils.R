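# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a stream index
#'
#' Permutation-based procedures in this package (window scans, per-test
#' permutation streams) draw their random numbers from a child seed derived
#' from one master seed and an integer stream counter, so that results for
#' stream `k` do not depend on how many other streams ran before it or on
#' execution order.
#'
#' The derivation seeds R's RNG with the master seed, draws `index + 1`
#' integers and keeps the last, leaving the caller's RNG state untouched.
#'
#' @param seed master seed (integer, below 2^31).
#' @param index non-negative stream counter.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index),
            index >= 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  as.integer(sample.int(2147483646L, index + 1L)[index + 1L])
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run code with a local RNG seeded by `seed`; caller's RNG state preserved.
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Strict upper triangle of a square matrix, column-major (R's upper.tri order).
ut <- function(m) m[upper.tri(m)]

# Intersect and sort sample ids across two or more labeled objects; message
# the intersection so label alignment is always visible in logs.
align_ids <- function(..., what = "samples") {
  sets <- list(...)
  common <- Reduce(intersect, sets)
  common <- sort(common)
  if (length(common) < length(sets[[1L]]) ||
      any(vapply(sets, length, 1L) != length(common))) {
    message(sprintf("aligning %s: %d in common (inputs had %s)", what,
                    length(common),
                    paste(vapply(sets, length, 1L), collapse = ", ")))
  }
  common
}

stop_gs <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_gs <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Format numbers so that read.delim round-trips them bit-identically.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}
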