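# internal numeric helpers

# z-score with the degenerate-series convention: a constant (or zero-variance)
# series maps to all zeros with a warning, never to NaN.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warn("z-score of a (near-)constant series returned as zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# row-wise z-score of a matrix (voxels or subjects in rows, TRs in columns)
zscore_rows <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L)
  mu <- rowMeans(m)
  xc <- m - mu
  s <- sqrt(rowSums(xc^2) / (ncol(m) - 1L))
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    warn(sprintf("%d constant row(s) z-scored to zeros", sum(bad)))
    s[bad] <- Inf
  }
  xc / s
}

assert_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    abort(sprintf("`%s` must be a single positive integer, got %s",
                  name, paste(format(x), collapse = ", ")))
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single value in [0, 1]", name))
  as.numeric(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; a NULL seed uses
# (and advances) the session RNG. Stage seeds are derived additively so that
# e.g. changing the bootstrap draw count does not perturb the phase null.
with_stage_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}
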