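# Internal helpers shared across modules.

# Deterministic sub-seed for a named stream, so that adding a new draw stream
# never perturbs earlier ones. Polynomial string hash folded into [1, 2^31-2].
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer(((as.numeric(seed) %% 2147483647) * 2654435 + h) %% 2147483646 + 1)
}

# Evaluate expr with a local RNG state seeded from (seed, stream name).
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant column")
  (x - mean(x)) / s
}

# For generator predictors: a constant design column contributes nothing
# (centered at 0) rather than erroring, so single-level designs still run.
zscore_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

minmax01 <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r))) stop("column has no finite values")
  if (r[1] == r[2]) stop("degenerate input: constant column cannot be min-max standardized")
  (x - r[1]) / (r[2] - r[1])
}

# Polynomial hash of a character scalar, as 8 hex digits; used for config
# manifests (not cryptographic).
fnv1a <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
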