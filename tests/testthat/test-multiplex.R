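make_net <- function(n = 5, seed = 1) {
  set.seed(seed)
  mk <- function() {
    m <- matrix(runif(n * n) * (runif(n * n) < 0.5), n, n)
    diag(m) <- 0
    m
  }
  multiplex(list(ActS = mk(), TfS = mk(), ActO = mk(), TfO = mk()),
            level = "alpha")
}

test_that("the multiplex constructor enforces its invariants", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  expect_s3_class(multiplex(list(A = m)), "multiplex")
  bad <- m; bad[1, 2] <- -1
  expect_error(multiplex(list(A = bad)), "negative")
  bad2 <- m; bad2[1, 1] <- 1
  expect_error(multiplex(list(A = bad2)), "self-links")
  expect_error(multiplex(list(A = m, B = matrix(0, 2, 2))), "square")
  expect_error(multiplex(list(A = m), level = "delta"), "level")
})

test_that("aggregation builds the S/O/T hierarchy consistently", {
  net <- make_net()
  expect_equal(aggregate_layers(net, "ActS"), net$layers$ActS)
  expect_error(aggregate_layers(net, "Nope"), "unknown")
  full <- add_hierarchy(net)
  expect_equal(full$layers$S + full$layers$O, full$layers$T,
               tolerance = 1e-12)
  expect_equal(full$layers$T,
               Reduce(`+`, full$layers[c("ActS", "TfS", "ActO", "TfO")]),
               tolerance = 1e-12)
  expect_equal(unname(full$level),
               c("alpha", "alpha", "alpha", "alpha", "beta", "beta",
                 "gamma"))
  # disjoint supports: density of the sum is the sum of densities
  a <- matrix(0, 4, 4); a[1, 2] <- 1; a[2, 3] <- 2
  b <- matrix(0, 4, 4); b[3, 4] <- 1; b[4, 1] <- 5
  nd <- multiplex(list(A = a, B = b))
  d <- layer_descriptors(nd)
  ds <- layer_descriptors(multiplex(list(AB = a + b)))
  expect_equal(ds$density, sum(d$density))
})

test_that("strengths obey the directed conventions and linearity", {
  m <- matrix(0, 3, 3); m[1, 2] <- 3
  net <- multiplex(list(A = m))
  st <- strengths(net)
  expect_equal(st$out_strength["N1", "A"], 3)
  expect_equal(st$in_strength["N2", "A"], 3)
  expect_equal(st$total_strength["N1", "A"], 3)
  expect_equal(st$total_strength["N3", "A"], 0)

  net4 <- add_hierarchy(make_net(seed = 2))
  st4 <- strengths(net4)
  # conservation: total in-strength equals total out-strength per layer
  expect_equal(colSums(st4$in_strength), colSums(st4$out_strength))
  # overlapping degree over {S, O} equals the strength on T
  so <- strengths(net4, layers = c("S", "O"))
  expect_equal(so$overlapping$o_total,
               unname(st4$total_strength[, "T"]), tolerance = 1e-12)
  # aggregation linearity
  ab <- aggregate_layers(net4, c("ActS", "ActO"))
  stab <- strengths(multiplex(list(AB = ab)))
  expect_equal(stab$in_strength[, "AB"],
               st4$in_strength[, "ActS"] + st4$in_strength[, "ActO"])
})

test_that("layer descriptors report weight and off-diagonal density", {
  empty <- multiplex(list(E = matrix(0, 4, 4)))
  de <- layer_descriptors(empty)
  expect_equal(de$weight, 0)
  expect_equal(de$density, 0)
  full <- matrix(1, 4, 4); diag(full) <- 0
  df <- layer_descriptors(multiplex(list(F = full)))
  expect_equal(df$weight, 12)
  expect_equal(df$density, 1)
  # a planted 0.5-density layer lands within 3 binomial SEs
  net <- generate_multiplex(90, 1, density = 0.5, seed = 12)
  d <- layer_descriptors(net)$density
  se <- sqrt(0.25 / (90 * 89))
  expect_lt(abs(d - 0.5), 3 * se)
})

test_that("a multiplex round-trips through the directory bundle", {
  net <- add_hierarchy(make_net(seed = 3))
  dir <- withr::local_tempdir()
  write_multiplex(net, dir)
  back <- read_multiplex(dir)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$level, net$level)
  for (nm in names(net$layers))
    expect_equal(back$layers[[nm]], net$layers[[nm]], tolerance = 1e-9)
})
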