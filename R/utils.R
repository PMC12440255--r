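# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so generators are pure functions of their
# seed argument.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FNV-1a over the serialized object; stable provenance fingerprint without an
# external digest dependency.
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  h <- 2166136261
  for (b in as.integer(raw)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)   # xor touches low byte only
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# Running peak-to-peak (max - min) over sliding windows of length k.
rolling_ptp <- function(x, k) {
  n <- length(x)
  if (k < 2L || k > n) stop_arg("window must span at least 2 and at most length(x) samples")
  e <- stats::embed(x, k)           # rows: x[k:n], x[k-1:n-1], ...
  apply(e, 1L, max) - apply(e, 1L, min)
}
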