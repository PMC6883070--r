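# Internal helpers: seed management and small numerics.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# Deterministically combine a base seed with integers/strings into a single
# seed in [1, 2^31 - 2]. Polynomial rolling hash over the UTF-8 bytes of the
# printed arguments, modulo the Mersenne prime 2^31 - 1 (kept in double
# precision; all intermediates stay below 2^53).
derive_seed <- function(base_seed, ...) {
  m <- 2147483647
  h <- as.numeric(base_seed) %% m
  for (part in list(...)) {
    for (b in utf8ToInt(paste0("|", paste(format(part), collapse = ",")))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h %% (m - 1)) + 1L
}

# Sample standard deviation; 0 for a single observation (degenerate runs are
# flagged by callers).
sd_or_zero <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
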