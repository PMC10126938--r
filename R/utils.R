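# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG state, restoring the caller's state on exit.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          allow_infinite = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L &&
    (allow_infinite || is.finite(x)) && !is.na(x)
  if (!ok || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  x
}

# Unit-normalize columns and make the largest-|entry| component of each
# column positive.  Deterministic signs are needed so that convergence norms
# on successive projection matrices are meaningful.
.fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    M[, j] <- v
  }
  M
}

.cosine <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# Zero-phase FIR filtering of every column of `x` with a symmetric
# odd-length kernel; edges handled by reflection padding.
.fir_zerophase <- function(x, kernel) {
  x <- as.matrix(x)
  L <- length(kernel)
  half <- (L - 1L) %/% 2L
  n <- nrow(x)
  if (n < 2L) return(x)
  pad <- min(half, n - 1L)
  top <- x[rev(seq_len(pad) + 1L), , drop = FALSE]
  bot <- x[n - seq_len(pad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2L)
  y <- as.matrix(y)[pad + seq_len(n), , drop = FALSE]
  y
}
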