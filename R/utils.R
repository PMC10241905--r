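#' @keywords internal
"_PACKAGE"

## Sleep/wake states used throughout the package.
PF_STATES <- c("NREM", "REM", "LEFT_OPEN", "RIGHT_OPEN", "BOTH_OPEN")
PF_UNSCORED <- "UNSCORED"

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so package functions are reproducible without
#' clobbering the caller's random stream.
#'
#' @param seed Integer seed (may be NULL to use the current stream).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed derivation: one master seed drives every
## artifact of a session; stream indices separate the consumers.
## Kept strictly below 2^31 - 1.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## FNV-1a 32-bit hash of a character scalar; used for provenance records.
## h is carried as a double in [0, 2^32); the xor only touches the low byte.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}
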