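# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the current state untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a base seed and a string tag, stable across
# sessions and below 2^31. NULL base propagates NULL (unseeded).
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 31 + v) %% 1982627311
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Median absolute deviation as a plain median of absolute deviations from
# the median; `constant` defaults to 1 (no normal-consistency scaling).
mad_raw <- function(x, constant = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  constant * median(abs(x - median(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
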