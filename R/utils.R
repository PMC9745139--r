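# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. A single user-facing seed fans out to per-stage child seeds via
# `child_seed()` so stages can be regenerated independently.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic child seed derived from (seed, stage label); kept within
# 32-bit integer range.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 131) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1) {
  length(x) == 1 && is.finite(x) && x == round(x) && x >= min
}

# Multiply column j of M by v[j] without forming diag(v).
colscale <- function(M, v) {
  M * rep(v, each = nrow(M))
}

# Column sums grouped as a length-ncol vector (alias kept for readability
# at call sites in the backward passes).
colsums <- function(M) .colSums(M, nrow(M), ncol(M))
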