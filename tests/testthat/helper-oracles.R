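# Independent reference implementations used as oracles.  These are
# deliberately written as plain double loops over state combinations /
# node triples, independent of the package's vectorized paths.

# Plug-in transfer entropy (k = l = 1) by direct summation over the 27
# state triples.
oracle_te <- function(a, b) {
  Tt <- length(a)
  x <- a[-Tt]; yb <- b[-Tt]; yn <- b[-1]
  tot <- 0
  for (aa in -1:1) for (bb in -1:1) for (cc in -1:1) {
    n_abc <- sum(x == aa & yb == bb & yn == cc)
    if (n_abc == 0) next
    n_ab <- sum(x == aa & yb == bb)
    n_bc <- sum(yb == bb & yn == cc)
    n_b <- sum(yb == bb)
    tot <- tot + (n_abc / (Tt - 1)) * log((n_abc / n_ab) / (n_bc / n_b))
  }
  tot
}

# Single-rule local TE by direct frequency counting.
oracle_rule_te <- function(a, b, aa, bb, cc, clamp = TRUE) {
  Tt <- length(a)
  x <- a[-Tt]; yb <- b[-Tt]; yn <- b[-1]
  n_abc <- sum(x == aa & yb == bb & yn == cc)
  if (n_abc == 0) return(0)
  n_ab <- sum(x == aa & yb == bb)
  n_bc <- sum(yb == bb & yn == cc)
  n_b <- sum(yb == bb)
  v <- (n_abc / (Tt - 1)) * log((n_abc / n_ab) / (n_bc / n_b))
  if (clamp && v < 0) 0 else v
}

# Exhaustive triad-pattern scorer: enumerates ordered triples, applies
# the double-link exclusion on the union of the pattern's layers, and
# dedupes physical instances by their (edge, layer) set.
oracle_subgraph <- function(net, pat) {
  n <- length(net$nodes)
  lys <- c(pat$l1, pat$l2, pat$l3)
  U <- Reduce(`+`, net$layers[unique(lys)])
  seen <- character(0)
  cnt <- 0; isum <- 0; csum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    e <- if (pat$kind == "Flux") list(c(i, j), c(j, k), c(i, k))
         else list(c(i, j), c(j, k), c(k, i))
    w <- vapply(1:3, function(q)
      net$layers[[lys[q]]][e[[q]][1], e[[q]][2]], 0)
    if (any(w <= 0)) next
    if (any(vapply(e, function(p) U[p[2], p[1]] > 0, TRUE))) next
    key <- paste(sort(vapply(1:3, function(q)
      paste(e[[q]][1], e[[q]][2], lys[q]), "")), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    cnt <- cnt + 1
    gm <- prod(w)^(1 / 3)
    isum <- isum + gm
    csum <- csum + 3 * gm / sum(w)
  }
  list(n_instances = cnt, intensity = isum,
       coherence = if (cnt > 0) csum / cnt else NA_real_)
}

# Directed weighted modularity by a literal double loop.
oracle_Q <- function(W, labels) {
  m <- sum(W)
  s_in <- colSums(W); s_out <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W)))
    if (labels[i] == labels[j])
      q <- q + W[i, j] - s_in[i] * s_out[j] / m
  q / m
}

# Best label agreement between two partitions of the same nodes, over
# all permutations of the smaller label set (used for <= 4 communities).
label_agreement <- function(found, truth) {
  ft <- unique(found); tt <- unique(truth)
  if (length(ft) > 6) return(mean(found == truth))
  best <- 0
  for (p in asplit(gtools_permutations(length(tt)), 1)) {
    mapped <- tt[p][match(found, ft)]
    if (length(ft) <= length(tt))
      best <- max(best, mean(mapped == truth, na.rm = TRUE))
  }
  best
}

# Minimal permutations generator (avoids extra dependencies).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# Random ternary sequence.
rtern <- function(n, prob = c(1, 1, 1) / 3) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = prob)
}
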