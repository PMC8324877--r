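test_that("generation is deterministic given the seed and matches marginals", {
  cfg <- generator_config(8, 2000, baseline = c(0.2, 0.5, 0.3), seed = 33)
  s1 <- generate_ternary_dynamics(cfg)
  s2 <- generate_ternary_dynamics(cfg)
  expect_identical(s1, s2)
  s3 <- generate_ternary_dynamics(generator_config(8, 2000,
                                                   baseline = c(0.2, 0.5, 0.3),
                                                   seed = 34))
  expect_false(identical(s1, s3))
  # baseline state frequencies within 3 standard errors
  for (st in c(-1L, 0L, 1L)) {
    p <- c(`-1` = 0.2, `0` = 0.5, `1` = 0.3)[[as.character(st)]]
    phat <- mean(s1 == st)
    se <- sqrt(p * (1 - p) / length(s1))
    expect_lt(abs(phat - p), 3 * se)
  }
})

test_that("a planted deterministic coupling reaches its analytic TE limit", {
  # coupling (A -> B, rule (1,0>1), p = 1), A i.i.d. uniform on {0, 1}:
  # stationary P(B = 1) = 3/5, so the rule's contribution converges to
  # P(A=1)P(B=0) * ln[1 / P(B'=1|B=0)] = 0.2 * ln(4/3); value frozen from
  # the frequency-counting oracle on a length-1e5 realization.
  cfg <- generator_config(2, 1e5, baseline = c(0, 0.5, 0.5),
                          couplings = list(coupling(1, 2,
                                                    rule_spec(1, 0, 1), 1)),
                          seed = 13)
  s <- generate_ternary_dynamics(cfg)
  v_pkg <- rule_local_te(s[1, ], s[2, ], rule_spec(1, 0, 1))
  v_oracle <- oracle_rule_te(s[1, ], s[2, ], 1, 0, 1)
  expect_equal(v_pkg, v_oracle, tolerance = 1e-12)
  expect_equal(v_pkg, 0.2 * log(4 / 3), tolerance = 0.01)
})

test_that("couplings with overlapping antecedents onto one target conflict", {
  expect_error(generator_config(3, 100, couplings = list(
    coupling(1, 3, rule_spec(1, 0, 1), 1),
    coupling(2, 3, rule_spec(-1, 0, -1), 1))), "conflict")
  expect_error(generator_config(3, 100, couplings = list(
    coupling(1, 3, rule_spec(1, 0, 1), 1),
    coupling(1, 3, rule_spec(1, 0, -1), 0.5))), "conflict")
  # same source, different source states: jointly unsatisfiable, allowed
  cfg <- generator_config(3, 100, couplings = list(
    coupling(1, 3, rule_spec(1, 0, 1), 1),
    coupling(1, 3, rule_spec(0, 0, 0), 1)))
  expect_s3_class(cfg, "generator_config")
  expect_error(coupling(2, 2, rule_spec(1, 0, 1)), "differ")
  expect_error(coupling(1, 2, rule_spec(1, 0, 1), 1.2), "probability")
})

test_that("the continuous wrapper round-trips through discretization", {
  set.seed(3)
  s0 <- generate_ternary_dynamics(
    generator_config(90, 240, baseline = c(0.2, 0.6, 0.2), seed = 91))
  x <- wrap_continuous(s0, 0.1, seed = 5)
  rec1 <- mean(discretize(zscore_rows(x), 1) == unclass(s0))
  expect_gte(rec1, 0.99)
  # recovery degrades monotonically with the wrapper noise
  x2 <- wrap_continuous(s0, 0.2, seed = 5)
  rec2 <- mean(discretize(zscore_rows(x2), 1) == unclass(s0))
  expect_lte(rec2, rec1)
  # an all-zero state matrix stays all-zero under direct thresholding
  z0 <- wrap_continuous(ternary_series(matrix(0L, 4, 50)), 0.1, seed = 2)
  expect_true(all(discretize(z0, 1) == 0L))
  expect_error(wrap_continuous(s0, 0), "positive")
})

test_that("planted couplings rank at the top of their rule slice", {
  hits <- 0
  for (sd in 1:10) {
    cfg <- generator_config(15, 5000, baseline = c(0.25, 0.5, 0.25),
                            couplings = list(
                              coupling(1, 2, rule_spec(1, 0, 1), 0.9)),
                            seed = sd)
    s <- generate_ternary_dynamics(cfg)
    tens <- build_rule_tensor(list(s))
    slice <- tens[1, , , rule_index(c(1, 0, 1)), 1]
    off <- row(slice) != col(slice)
    rk <- rank(-slice[off])[which((row(slice) == 1 & col(slice) == 2)[off])]
    hits <- hits + (rk <= max(1, ceiling(0.01 * sum(off))))
  }
  expect_gte(hits, 9)
})

test_that("multiplex generation honours density and reciprocity bias", {
  # bias +1: every link reciprocated; equal weights give r = 1
  net1 <- generate_multiplex(12, 1, density = 0.4, reciprocity_bias = 1,
                             weight_dist = list(dist = "constant",
                                                value = 2), seed = 4)
  W <- net1$layers[[1]]
  expect_true(all((W > 0) == t(W > 0)))
  expect_equal(weighted_reciprocity(W, n_null = 10, seed = 1)$raw, 1)
  # bias -1 at density <= 0.5: no reciprocated pair, r = 0
  net2 <- generate_multiplex(12, 1, density = 0.4, reciprocity_bias = -1,
                             seed = 5)
  W2 <- net2$layers[[1]]
  expect_equal(sum((W2 > 0) & t(W2 > 0)), 0)
  expect_equal(weighted_reciprocity(W2, n_null = 10, seed = 1)$raw, 0)
  # determinism and density calibration
  net3 <- generate_multiplex(40, 2, density = 0.3, seed = 6)
  net3b <- generate_multiplex(40, 2, density = 0.3, seed = 6)
  expect_identical(net3$layers, net3b$layers)
  d <- mean(net3$layers[[1]][row(net3$layers[[1]]) !=
                               col(net3$layers[[1]])] > 0)
  se <- sqrt(0.3 * 0.7 / (40 * 39))
  expect_lt(abs(d - 0.3), 4 * se)
})
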