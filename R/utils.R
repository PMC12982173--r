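# Internal helpers shared across modules.

#' Derive a deterministic sub-seed from a global seed and a stream label
#'
#' All randomness in the package flows from one integer seed; each module
#' draws from its own named substream so that changing one module's draws
#' does not shift another's. The mixing is a small multiplicative hash kept
#' below 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed integer global seed
#' @param stream character label of the substream
#' @return integer sub-seed in [0, 2^31 - 2]
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# Run code under a local RNG state so callers' .Random.seed is untouched.
with_seed <- function(seed, code) {
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
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks used by the spec constructors
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop(sprintf("`%s` must be a numeric scalar", name), call. = FALSE)
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    stop(sprintf("`%s` must not be NA", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

# population SD (divides by n, not n - 1)
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Null-coalescing helper
#' @param a,b values; returns `b` when `a` is NULL
#' @name op-null-default
#' @export
`%||%` <- function(a, b) if (is.null(a)) b else a
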