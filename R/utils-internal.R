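# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise softmax; -Inf entries get exactly zero weight.
softmax_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so library calls do not perturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, mixed with a seed.
# Used for the deterministic per-id train/test assignment.
fnv1a32 <- function(s, seed = 0L) {
  b <- utf8ToInt(enc2utf8(s)) %% 256L
  h <- 2166136261
  p <- 16777619
  for (x in c(seed %% 256L, b)) {
    # xor only touches the low byte (x < 256); keeps h in double range
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(x))
    # 32-bit modular multiply split into 16-bit halves to stay inside the
    # exactly-representable double range
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
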