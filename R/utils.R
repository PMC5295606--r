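# Internal helpers shared across modules.

# Canonical unordered-pair key; "\r" cannot occur in trimmed gene ids.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic derivation of per-stage / per-replicate seeds from one master
# seed (Lehmer-style step, kept inside 32-bit signed integer range).
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.double(offset) * 69621) %% 2147483646 + 1)
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(trimws(x))) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  invisible(trimws(x))
}

# Map indices 1..n*(n-1)/2 to unordered pairs (i, j), i < j, in row-major
# order (1,2),(1,3),...,(1,n),(2,3),...  Used to sample random gene pairs
# without materialising the full pair list.
unrank_pairs <- function(idx, n) {
  if (n < 2L) stop("need at least two items to form pairs", call. = FALSE)
  csum <- cumsum(as.double(n - seq_len(n - 1L)))
  i <- findInterval(idx - 1, c(0, csum), rightmost.closed = FALSE, left.open = FALSE)
  offset <- idx - c(0, csum)[i]
  j <- i + offset
  cbind(i = as.integer(i), j = as.integer(j))
}
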