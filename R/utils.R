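# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG afterwards, so seeded helpers never perturb the
# global random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded sub-seed from a user seed and a stream offset; keeps
# every derived seed a valid 32-bit integer.
sub_seed <- function(seed, offset) {
  (as.double(seed) * 1009 + offset * 9973) %% 2147483647
}

# One-sided (greater) Welch test from summary statistics; falls back to
# a mean comparison when both variances vanish.  Returns the p-value and
# whether the degenerate fallback was taken.
welch_greater <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  if (!is.finite(se2) || se2 <= 0 || n1 < 2 || n2 < 2)
    return(list(p = if (isTRUE(m1 > m2)) 0 else 1, degenerate = TRUE))
  tval <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(p = stats::pt(tval, df, lower.tail = FALSE), degenerate = FALSE)
}

# Off-diagonal logical mask of an n x n matrix.
offdiag <- function(n) {
  m <- matrix(TRUE, n, n)
  diag(m) <- FALSE
  m
}
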