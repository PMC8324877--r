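test_that("directed weighted Q matches its defining sum", {
  # two disjoint 2-node directed cycles under the true partition
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
  expect_equal(directed_weighted_Q(W, c(1, 1, 2, 2)), 0.5)
  # the single-community partition is exactly 0
  expect_equal(directed_weighted_Q(W, rep(1, 4)), 0)
  # random matrices against the double-loop oracle
  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:9, 1)
    Wr <- matrix(runif(n * n) * (runif(n * n) < 0.6), n, n)
    diag(Wr) <- 0
    labs <- sample(1:3, n, replace = TRUE)
    expect_equal(directed_weighted_Q(Wr, labs), oracle_Q(Wr, labs),
                 tolerance = 1e-12)
    # relabelling invariance
    expect_equal(directed_weighted_Q(Wr, labs),
                 directed_weighted_Q(Wr, c("x", "y", "z")[labs]),
                 tolerance = 1e-14)
    # all-singletons partition is never positive for nonnegative weights
    expect_lte(directed_weighted_Q(Wr, seq_len(n)), 1e-14)
  }
  expect_error(directed_weighted_Q(matrix(0, 3, 3), 1:3), "undefined")
})

test_that("community search recovers separable structure", {
  set.seed(15)
  # two disconnected equal blocks: unambiguous optimum
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- matrix(runif(16), 4); W[5:8, 5:8] <- matrix(runif(16), 4)
  diag(W) <- 0
  fc <- find_communities(W, seed = 1)
  expect_equal(fc$n_communities, 2L)
  expect_equal(length(unique(fc$labels[1:4])), 1L)
  expect_equal(length(unique(fc$labels[5:8])), 1L)
  expect_gt(fc$Q, 0)
  # complete uniform matrix: no structure, Q effectively 0
  Wu <- matrix(1, 10, 10); diag(Wu) <- 0
  fu <- find_communities(Wu, seed = 2)
  expect_lte(fu$Q, 1e-10)
  # deterministic given seed
  expect_identical(find_communities(W, seed = 7)$labels,
                   find_communities(W, seed = 7)$labels)
})

test_that("planted three-block networks are recovered", {
  agree <- sapply(1:10, function(sd) {
    set.seed(1000 + sd)
    n <- 24
    W <- matrix(runif(n * n) * 0.05, n, n)
    truth <- rep(1:3, each = 8)
    for (b in 1:3) {
      idx <- which(truth == b)
      W[idx, idx] <- matrix(runif(64), 8)
    }
    diag(W) <- 0
    fc <- find_communities(W, seed = sd)
    label_agreement(unname(fc$labels), truth)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("modularity significance separates structure from permutation", {
  set.seed(16)
  n <- 24
  W <- matrix(runif(n * n) * 0.05, n, n)
  for (b in 0:2) {
    idx <- b * 8 + 1:8
    W[idx, idx] <- matrix(runif(64), 8)
  }
  diag(W) <- 0
  ms <- modularity_significance(W, n_replicates = 100, seed = 3)
  expect_lte(ms$p_value, 0.05)
  # identical seed, identical null statistics
  ms2 <- modularity_significance(W, n_replicates = 100, seed = 3)
  expect_identical(ms$null_Q, ms2$null_Q)
})

test_that("directed weighted Q agrees with igraph's implementation", {
  skip_if_not_installed("igraph")
  set.seed(18)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    W <- matrix(runif(n * n) * (runif(n * n) < 0.5), n, n); diag(W) <- 0
    labs <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "directed",
                                             weighted = TRUE)
    q_ig <- igraph::modularity(g, membership = labs,
                               weights = igraph::E(g)$weight,
                               directed = TRUE)
    expect_equal(directed_weighted_Q(W, labs), q_ig, tolerance = 1e-12)
  }
})
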