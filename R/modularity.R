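#' Directed weighted modularity of a partition
#'
#' Newman's directed modularity with strengths in place of degrees:
#' \deqn{Q = \frac{1}{m_w} \sum_{ij}
#'   \left[ W_{ij} - \frac{s_i^{in} s_j^{out}}{m_w} \right]
#'   \delta(c_i, c_j),}
#' where \eqn{m_w} is the total weight, \eqn{s^{in}} / \eqn{s^{out}} are
#' in-/out-strengths and the sum runs over all ordered node pairs within
#' a community.  Q is exactly 0 for the single-community partition.
#'
#' @param W Square nonnegative weight matrix (row = source).
#' @param labels Community label per node (any atomic type).
#' @return Scalar Q; error when the total weight is zero.
#' @export
#' @examples
#' W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
#' directed_weighted_Q(W, c(1, 1, 2, 2))  # 0.5
directed_weighted_Q <- function(W, labels) {
  stopifnot(nrow(W) == ncol(W), length(labels) == nrow(W))
  m <- sum(W)
  if (m == 0) stop("modularity undefined: total weight is zero")
  s_in <- colSums(W)
  s_out <- rowSums(W)
  labs <- as.integer(factor(labels))
  q <- 0
  for (c in unique(labs)) {
    idx <- labs == c
    q <- q + sum(W[idx, idx]) - sum(s_in[idx]) * sum(s_out[idx]) / m
  }
  q / m
}

#' Greedy community detection for directed weighted networks
#'
#' Louvain-style maximization of [directed_weighted_Q()]: repeated local
#' node moves (each node joins the community with the best modularity
#' gain; ties broken by the lowest community index) followed by
#' aggregation of communities into super-nodes, until no move improves
#' Q.  The sweep order is drawn once from the seed, making the result
#' deterministic given the seed.
#'
#' @param W Square nonnegative weight matrix.
#' @param seed Integer seed (default 1).
#' @return A list of class `modularity_partition`: `labels` (integer
#'   community per node, named by row names), `Q`, `n_communities`.
#' @export
find_communities <- function(W, seed = 1L) {
  stopifnot(nrow(W) == ncol(W))
  if (any(W < 0)) stop("weights must be nonnegative")
  n <- nrow(W)
  m <- sum(W)
  if (m == 0) stop("community detection undefined: total weight is zero")
  labels <- with_seed(seed, louvain_directed(W, sample.int(n)))
  labels <- as.integer(factor(labels))  # compact 1..k
  names(labels) <- rownames(W) %||% paste0("N", seq_len(n))
  structure(list(labels = labels, Q = directed_weighted_Q(W, labels),
                 n_communities = length(unique(labels))),
            class = "modularity_partition")
}

#' @export
print.modularity_partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities, Q = %.4f", x$n_communities, x$Q))
  if (!is.null(x$p_value))
    cat(sprintf("  (null Q %.4f +/- %.4f, p = %.4g)", x$null_mean,
                x$null_sd, x$p_value))
  cat("\n")
  invisible(x)
}

# One Louvain level: local moving on W with the given sweep order, then
# recursion on the aggregated community matrix.
louvain_directed <- function(W, order) {
  n <- nrow(W)
  m <- sum(W)
  s_in <- colSums(W)
  s_out <- rowSums(W)
  labs <- seq_len(n)
  S_in <- s_in
  S_out <- s_out
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in order) {
      cv <- labs[v]
      # detach v from its community
      S_in[cv] <- S_in[cv] - s_in[v]
      S_out[cv] <- S_out[cv] - s_out[v]
      # weight between v and each community (both directions)
      w_out_v <- W[v, ]
      w_in_v <- W[, v]
      conn <- rowsum(w_out_v + w_in_v, labs)          # by community label
      comm_ids <- as.integer(rownames(conn))
      link <- numeric(max(labs))
      link[comm_ids] <- conn[, 1L]
      link[labs[v]] <- link[labs[v]] - 2 * W[v, v]
      gains <- link[comm_ids] -
        (s_in[v] * S_out[comm_ids] + s_out[v] * S_in[comm_ids]) / m
      # candidate set: communities v touches plus its own
      best <- comm_ids[which.max(gains)]
      gv <- max(gains)
      g_stay <- gains[comm_ids == cv]
      if (length(g_stay) == 0L) g_stay <- 0
      if (gv > g_stay + 1e-12) {
        # tie-break: lowest community index among equal gains
        best <- min(comm_ids[gains >= gv - 1e-12])
        labs[v] <- best
        moved <- TRUE
        improved_any <- TRUE
      }
      S_in[labs[v]] <- S_in[labs[v]] + s_in[v]
      S_out[labs[v]] <- S_out[labs[v]] + s_out[v]
    }
    if (!moved) break
  }
  comm <- as.integer(factor(labs))
  k <- max(comm)
  if (!improved_any || k == n || k == 1L)
    return(comm)
  # aggregate and recurse
  agg <- matrix(0, k, k)
  for (c1 in seq_len(k))
    for (c2 in seq_len(k))
      agg[c1, c2] <- sum(W[comm == c1, comm == c2, drop = FALSE])
  upper <- louvain_directed(agg, seq_len(k))
  upper[comm]
}

#' Randomization significance of modularity
#'
#' Re-optimizes communities on randomized copies of the weight matrix
#' and reports the upper-tail empirical p-value of the observed Q.
#' `"permute"` shuffles the off-diagonal weights uniformly (the
#' combinatorial randomization appropriate for dense averaged matrices);
#' `"in_strength"` preserves every node's in-strength (for sparse
#' subject-level layers).
#'
#' @param W Square nonnegative weight matrix.
#' @param n_replicates Null replicates (default 100).
#' @param randomization `"permute"` (default) or `"in_strength"`.
#' @param seed Integer seed.
#' @return A `modularity_partition` (observed partition) with extra
#'   fields `null_mean`, `null_sd`, `null_Q`, `p_value`, `n_replicates`.
#' @export
modularity_significance <- function(W, n_replicates = 100L,
                                    randomization = c("permute",
                                                      "in_strength"),
                                    seed = 1L) {
  randomization <- match.arg(randomization)
  stopifnot(n_replicates >= 1L)
  obs <- find_communities(W, seed = seed)
  null_q <- with_seed(sub_seed(seed, 77), vapply(seq_len(n_replicates),
    function(r) {
      Wr <- randomize_weights(W, randomization)
      find_communities(Wr, seed = sub_seed(seed, r))$Q
    }, 0))
  obs$null_Q <- null_q
  obs$null_mean <- mean(null_q)
  obs$null_sd <- stats::sd(null_q)
  obs$p_value <- (1 + sum(null_q >= obs$Q)) / (1 + n_replicates)
  obs$n_replicates <- n_replicates
  obs
}
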