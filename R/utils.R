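# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Draw `n` derived seeds from a master seed; all stay well below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2^30, n))
}

abort_fcga <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fcga_error"))
}

# Column-wise deterministic sign convention: the entry of largest absolute
# value in `key` (one column per component) must be positive.
fix_signs <- function(scores, key) {
  for (j in seq_len(ncol(key))) {
    i <- which.max(abs(key[, j]))
    if (key[i, j] < 0) {
      key[, j] <- -key[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, key = key)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
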