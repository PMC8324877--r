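# Fabricate a rule tensor whose link profiles follow prescribed bases:
# sign-symmetric rule pairs share a profile, the two taxonomy groups are
# anti-correlated.
make_profile_tensor <- function(n_sub = 3, R = 6, noise = 0.02, seed = 1) {
  set.seed(seed)
  tax <- rule_taxonomy()
  # one shared profile per group (G1 and its mirror for G2) with a
  # smaller label-specific component, so the nesting is group > label
  P <- matrix(runif(R * R), R, R)
  jit <- function() matrix(rnorm(R * R, sd = 0.1), R, R)
  base <- list(ActS = P + jit(), TfS = P + jit(),
               ActO = (max(P) - P) + jit(), TfO = (max(P) - P) + jit())
  v <- array(0, c(n_sub, R, R, 27, 1),
             dimnames = list(paste0("S", seq_len(n_sub)),
                             paste0("R", seq_len(R)),
                             paste0("R", seq_len(R)),
                             all_rules()$id, "1"))
  for (i in seq_len(8)) {
    for (s in seq_len(n_sub)) {
      m <- base[[tax$label[i]]] + matrix(rnorm(R * R, sd = noise), R, R)
      m <- pmax(m, 0); diag(m) <- 0
      v[s, , , tax$index[i], 1] <- m
    }
  }
  structure(v, thresholds = 1, history_k = 1L, history_l = 1L,
            class = c("rule_tensor", "array"))
}

test_that("rule correlation is Pearson on subject-mean link profiles", {
  tens <- make_profile_tensor(noise = 1e-9)
  tax <- rule_taxonomy()
  cm <- rule_correlation(tens, tax)
  expect_equal(diag(cm), rep(1, 8), ignore_attr = TRUE)
  expect_equal(cm, t(cm))
  # sign partners share a profile: correlation 1
  expect_equal(cm["1,0>1", "-1,0>-1"], 1, tolerance = 1e-6)
  # opposite-group partners are anti-correlated
  expect_lt(cm["1,0>1", "1,0>-1"], 0)
  # zero-variance profile reports missing
  tens0 <- tens
  tens0[, , , rule_index(c(1, 0, 1)), 1] <- 0.5
  for (s in 1:3) diag(tens0[s, , , rule_index(c(1, 0, 1)), 1]) <- 0
  cm0 <- rule_correlation(tens0, tax)
  expect_true(all(is.na(cm0["1,0>1", ])))
  expect_error(cluster_rules(cm0), "1,0>1")
})

test_that("hierarchical clustering recovers the nested rule structure", {
  tens <- make_profile_tensor(noise = 0.02)
  cm <- rule_correlation(tens, rule_taxonomy())
  cl <- cluster_rules(cm)
  tax <- rule_taxonomy()
  # 2-cut separates the same-state group from the opposite-state group
  g <- split(names(cl$cut2), cl$cut2)
  expect_setequal(vapply(g, function(ids)
    paste(sort(unique(tax$group[match(ids, tax$id)])), collapse = ""),
    ""), c("G1", "G2"))
  # 4-cut pairs each rule with its sign partner
  p <- split(names(cl$cut4), cl$cut4)
  expect_true(all(vapply(p, length, 0L) == 2))
  for (ids in p) {
    labs <- tax$label[match(ids, tax$id)]
    expect_equal(labs[1], labs[2])
  }
  # in particular (1,0>1) and (-1,0>-1) fall in the same first-level pair
  expect_equal(cl$cut4[["1,0>1"]], cl$cut4[["-1,0>-1"]])
})

test_that("rule layers sum the label's two local-TE slices", {
  set.seed(4)
  R <- 5
  v <- array(0, c(2, R, R, 27, 2),
             dimnames = list(paste0("S", 1:2), paste0("R", 1:R),
                             paste0("R", 1:R), all_rules()$id,
                             c("0.5", "1")))
  k_acts <- rule_index(c(1, 0, 1))
  m <- matrix(runif(R * R), R, R); diag(m) <- 0
  v[1, , , k_acts, 2] <- m
  v[2, , , k_acts, 2] <- m
  tens <- structure(v, thresholds = c(0.5, 1), history_k = 1L,
                    history_l = 1L, class = c("rule_tensor", "array"))
  net <- build_rule_layers(tens)
  expect_equal(unname(net$layers$ActS), m)
  expect_equal(sum(net$layers$ActO), 0)
  expect_equal(sum(net$layers$TfS), 0)
  d <- layer_descriptors(net)
  expect_true(all(d$density >= 0 & d$density <= 1))
})

test_that("the ActS layer is invariant under a global sign flip", {
  cps <- list(coupling(1, 2, rule_spec(1, 0, 1), 0.9),
              coupling(3, 4, rule_spec(-1, 0, -1), 0.9))
  s <- generate_ternary_dynamics(
    generator_config(6, 2000, baseline = c(0.3, 0.4, 0.3),
                     couplings = cps, seed = 8))
  flip <- ternary_series(-unclass(s))
  t1 <- build_rule_tensor(list(s))
  t2 <- build_rule_tensor(list(flip))
  n1 <- build_rule_layers(t1)
  n2 <- build_rule_layers(t2)
  # each label's two rules swap under the flip, so every layer persists
  for (lb in c("ActS", "TfS", "ActO", "TfO"))
    expect_equal(n1$layers[[lb]], n2$layers[[lb]], tolerance = 1e-12)
})
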