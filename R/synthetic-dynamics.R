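#' Planted rule coupling
#'
#' Declares that whenever the source node is in the rule's `a` state and
#' the target in its `b` state at step n, the target takes the rule's
#' `bnext` state at step n + 1 with probability `prob` (otherwise it
#' evolves by the baseline marginal).
#'
#' @param source,target Node indices (distinct).
#' @param rule A [rule_spec()] (or length-3 state vector).
#' @param prob Coupling probability in \[0, 1\].
#' @return A list of class `planted_coupling`.
#' @export
coupling <- function(source, target, rule, prob = 1) {
  if (source == target) stop("source and target must differ")
  if (prob < 0 || prob > 1) stop("coupling probability must be in [0, 1]")
  r <- as.integer(rule)
  rule_index(r)  # validates
  structure(list(source = as.integer(source), target = as.integer(target),
                 rule = rule_spec(r[1L], r[2L], r[3L]), prob = prob),
            class = "planted_coupling")
}

#' Configuration of the ternary-dynamics generator
#'
#' @param n_nodes Number of nodes (regions).
#' @param n_time Number of time points (>= 3).
#' @param baseline Probability triple over the states (-1, 0, 1), must
#'   sum to 1.
#' @param couplings List of [coupling()]s.  Couplings onto the same
#'   target with overlapping antecedents (same target state and a
#'   jointly satisfiable source condition) and different consequents are
#'   rejected as conflicting.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_nodes, n_time, baseline = c(1, 1, 1) / 3,
                             couplings = list(), seed = 1L) {
  if (n_time < 3L) stop("n_time must be >= 3")
  if (length(baseline) != 3L || any(baseline < 0) ||
      abs(sum(baseline) - 1) > 1e-8)
    stop("baseline must be a probability triple over (-1, 0, 1) summing to 1")
  for (cp in couplings) {
    if (!inherits(cp, "planted_coupling")) stop("couplings must be coupling()s")
    if (cp$source > n_nodes || cp$target > n_nodes)
      stop("coupling node index exceeds n_nodes")
  }
  # conflict check: overlapping antecedents onto one target
  if (length(couplings) > 1L) {
    for (u in seq_along(couplings)[-1L]) {
      for (v in seq_len(u - 1L)) {
        cu <- couplings[[u]]; cv <- couplings[[v]]
        if (cu$target != cv$target) next
        if (cu$rule[["b"]] != cv$rule[["b"]]) next
        joint <- cu$source != cv$source ||
          cu$rule[["a"]] == cv$rule[["a"]]
        if (joint && cu$rule[["bnext"]] != cv$rule[["bnext"]])
          stop(sprintf(
            "conflicting couplings onto node %d: rules %s and %s overlap",
            cu$target, rule_id(cu$rule[1], cu$rule[2], cu$rule[3]),
            rule_id(cv$rule[1], cv$rule[2], cv$rule[3])))
      }
    }
  }
  structure(list(n_nodes = as.integer(n_nodes), n_time = as.integer(n_time),
                 baseline = baseline, couplings = couplings,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate ternary-event dynamics with planted couplings
#'
#' Every node draws i.i.d. states from the baseline marginal; at each
#' step, each planted coupling whose antecedent pair holds fires with
#' its coupling probability and overrides the target's next baseline
#' draw with the rule's consequent state.  Uncoupled nodes are purely
#' i.i.d.; the whole realization is deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return A [ternary_series()] (`n_nodes` x `n_time`).
#' @export
#' @examples
#' cfg <- generator_config(3, 100, seed = 7)
#' s <- generate_ternary_dynamics(cfg)
#' identical(s, generate_ternary_dynamics(cfg))  # TRUE
generate_ternary_dynamics <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_nodes
  Tt <- config$n_time
  cps <- config$couplings
  S <- with_seed(config$seed, {
    S <- matrix(sample(c(-1L, 0L, 1L), n * Tt, replace = TRUE,
                       prob = config$baseline), n, Tt)
    if (length(cps)) {
      src <- vapply(cps, `[[`, 1L, "source")
      tgt <- vapply(cps, `[[`, 1L, "target")
      aS <- vapply(cps, function(cp) cp$rule[["a"]], 1L)
      bS <- vapply(cps, function(cp) cp$rule[["b"]], 1L)
      bN <- vapply(cps, function(cp) cp$rule[["bnext"]], 1L)
      pr <- vapply(cps, `[[`, 1, "prob")
      U <- matrix(stats::runif(length(cps) * (Tt - 1L)),
                  length(cps), Tt - 1L)
      for (t in seq_len(Tt - 1L)) {
        fire <- S[cbind(src, t)] == aS & S[cbind(tgt, t)] == bS &
          U[, t] <= pr
        if (any(fire)) S[cbind(tgt[fire], t + 1L)] <- bN[fire]
      }
    }
    S
  })
  ternary_series(S)
}

#' Render ternary states as continuous BOLD-like signals
#'
#' Each state s is drawn as `1.5 * s` plus Gaussian noise with the given
#' dispersion, so that z-scoring followed by 1-S.D. thresholding
#' recovers the planted states for small dispersions.  This exercises
#' the discretization stage on synthetic data.
#'
#' @param series A [ternary_series()] (or states matrix).
#' @param amplitude_sd Positive noise S.D. around the state amplitude.
#' @param seed Integer seed.
#' @return A numeric matrix of the same shape.
#' @export
wrap_continuous <- function(series, amplitude_sd, seed = 1L) {
  if (amplitude_sd <= 0) stop("amplitude_sd must be positive")
  s <- unclass(series)
  with_seed(seed,
            matrix(1.5 * as.numeric(s) +
                     stats::rnorm(length(s), sd = amplitude_sd),
                   nrow(s), ncol(s), dimnames = dimnames(s)))
}
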