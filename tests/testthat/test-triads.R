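test_that("pattern enumeration matches the closed-form counts", {
  for (M in 1:6) {
    lys <- paste0("L", seq_len(M))
    expect_equal(nrow(enumerate_triad_patterns(lys, 0, "Cycle")), M)
    expect_equal(nrow(enumerate_triad_patterns(lys, 0, "Flux")), M)
    expect_equal(nrow(enumerate_triad_patterns(lys, 1, "Cycle")),
                 if (M >= 2) M * (M - 1) else 0)
    expect_equal(nrow(enumerate_triad_patterns(lys, 1, "Flux")),
                 if (M >= 2) 3 * M * (M - 1) else 0)
    expect_equal(nrow(enumerate_triad_patterns(lys, 2, "Cycle")),
                 if (M >= 3) choose(M, 3) * 2 else 0)
    expect_equal(nrow(enumerate_triad_patterns(lys, 2, "Flux")),
                 if (M >= 3) M * (M - 1) * (M - 2) else 0)
  }
  # patterns are unique and orders are as labelled
  p <- enumerate_triad_patterns(4, 1)
  expect_equal(anyDuplicated(p$name), 0L)
  expect_true(all(apply(p[, c("l1", "l2", "l3")], 1,
                        function(r) length(unique(r))) == 2))
})

test_that("instance intensity and coherence follow the closed forms", {
  W <- matrix(0, 3, 3); W[1, 2] <- 2; W[2, 3] <- 4; W[1, 3] <- 8
  net <- multiplex(list(A = W))
  sc <- score_subgraph(net, enumerate_triad_patterns("A", 0, "Flux")[1, ])
  expect_equal(sc$n_instances, 1)
  expect_equal(sc$intensity, 4)
  expect_equal(sc$coherence, 6 / 7)
  # equal weights: coherence exactly 1
  We <- matrix(0, 3, 3); We[1, 2] <- We[2, 3] <- We[3, 1] <- 5
  nc <- multiplex(list(A = We))
  scc <- score_subgraph(nc, enumerate_triad_patterns("A", 0, "Cycle")[1, ])
  expect_equal(scc$n_instances, 1)
  expect_equal(scc$coherence, 1)
  expect_equal(scc$intensity, 5)
  # no instance: intensity 0, coherence undefined
  s0 <- score_subgraph(multiplex(list(A = matrix(0, 3, 3))),
                       enumerate_triad_patterns("A", 0, "Flux")[1, ])
  expect_equal(s0$intensity, 0)
  expect_true(is.na(s0$coherence))
})

test_that("the triad scan agrees with the exhaustive oracle", {
  set.seed(21)
  for (case in 1:20) {
    n <- sample(4:7, 1)
    bias <- runif(1, -0.5, 0.5)
    dens <- if (bias < 0) runif(1, 0.3, 0.45) else runif(1, 0.3, 0.8)
    net <- generate_multiplex(n, 2, density = dens,
                              reciprocity_bias = bias, seed = 100 + case)
    for (ord in 0:1) {
      pats <- enumerate_triad_patterns(c("L1", "L2"), ord)
      for (i in seq_len(nrow(pats))) {
        sc <- score_subgraph(net, pats[i, ])
        ob <- oracle_subgraph(net, pats[i, ])
        expect_equal(sc$n_instances, ob$n_instances)
        expect_equal(sc$intensity, ob$intensity, tolerance = 1e-12)
        if (!is.na(ob$coherence)) {
          expect_equal(sc$coherence, ob$coherence, tolerance = 1e-12)
          expect_gte(sc$coherence, 0)
          expect_lte(sc$coherence, 1)
        }
      }
    }
  }
})

test_that("triad randomization significance behaves at the extremes", {
  set.seed(3)
  # planted strong Flux instances on a weak background
  W1 <- matrix(runif(100) * 0.1 * (runif(100) < 0.3), 10, 10)
  diag(W1) <- 0
  for (i in seq(1, 7, by = 3)) {    # strong coherent triads
    W1[i, i + 1] <- 10; W1[i + 1, i + 2] <- 10; W1[i, i + 2] <- 10
    W1[i + 1, i] <- W1[i + 2, i + 1] <- W1[i + 2, i] <- 0
  }
  net <- multiplex(list(A = W1))
  pat <- enumerate_triad_patterns("A", 0, "Flux")
  sig <- subgraph_significance(net, pat, n_replicates = 100, seed = 5)
  expect_lte(sig$p_intensity, 0.05)
  # an absent pattern cannot beat any null
  empty <- multiplex(list(A = matrix(0, 10, 10), B = W1))
  patA <- enumerate_triad_patterns(c("A", "B"), 0, "Flux")[1, ]
  sigA <- subgraph_significance(empty, patA, n_replicates = 20, seed = 6)
  expect_equal(sigA$p_intensity, 1)
  # deterministic given the seed
  sig2 <- subgraph_significance(net, pat, n_replicates = 100, seed = 5)
  expect_equal(sig$p_intensity, sig2$p_intensity)
})

test_that("group-level triad significance separates signal from noise", {
  set.seed(8)
  mk <- function(seed, strong) {
    W <- matrix(runif(144) * 0.2 * (runif(144) < 0.4), 12, 12)
    diag(W) <- 0
    if (strong) {
      W[1, 2] <- W[2, 3] <- W[1, 3] <- 8
      W[2, 1] <- W[3, 2] <- W[3, 1] <- 0
    }
    multiplex(list(A = W))
  }
  nets <- lapply(1:5, function(i) mk(i, strong = TRUE))
  pat <- enumerate_triad_patterns("A", 0, "Flux")
  g <- triad_group_significance(nets, pat, n_null = 10, seed = 9)
  expect_lt(g$p_intensity, 0.05)
  expect_true(all(c("intensity", "intensity_sd", "coherence",
                    "coherence_sd") %in% names(g)))
})
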