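# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All exported stochastic operations funnel
# through this so that explicit seeds are the only source of randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed by fixed integer arithmetic
# (kept below 2^31 - 1 so it is always a valid R integer seed).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 69069 + as.double(i) * 9973 + 1) %% 2147483629)
}

# Midpoint between two coordinates, ties broken toward the lower coordinate.
midpoint <- function(a, b) floor((a + b) / 2)

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Length of the part of [start, end) that does not intersect [ex_start, ex_end).
interval_len_excluding <- function(start, end, ex_start, ex_end) {
  ov <- pmax(0, pmin(end, ex_end) - pmax(start, ex_start))
  (end - start) - ov
}
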