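#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible per-stage seed from a global seed and a stage label.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- as.double(seed %% 2147483647L)
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
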