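#' Generate a random directed weighted multiplex network
#'
#' Each layer draws its dyads independently: for every unordered node
#' pair the presence of the two directed links is governed by the link
#' density and a reciprocity bias that inflates (`> 0`) or suppresses
#' (`< 0`) the co-occurrence of i -> j and j -> i.  With bias +1 every
#' link is reciprocated; with bias -1 (and density <= 0.5) no pair is.
#' Link weights are i.i.d. from the named weight distribution.
#'
#' @param n_nodes Number of nodes.
#' @param n_layers Number of layers (default 1).
#' @param density Directed link density in (0, 1].
#' @param weight_dist Named distribution: `list(dist = "unif", min, max)`,
#'   `list(dist = "exp", rate)`, `list(dist = "lnorm", meanlog, sdlog)`
#'   or `list(dist = "constant", value)`.
#' @param reciprocity_bias Real in \[-1, 1\] (default 0: independent
#'   directions).
#' @param seed Integer seed; deterministic given the seed.
#' @param level Hierarchy tags for the layers (default `"alpha"`).
#' @return A [multiplex()] with layers `L1..Lm`.
#' @export
generate_multiplex <- function(n_nodes, n_layers = 1L, density = 0.3,
                               weight_dist = list(dist = "unif",
                                                  min = 0.5, max = 1.5),
                               reciprocity_bias = 0, seed = 1L,
                               level = "alpha") {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  if (abs(reciprocity_bias) > 1) stop("reciprocity_bias must be in [-1, 1]")
  p <- density
  p_both <- if (reciprocity_bias >= 0)
    p^2 + reciprocity_bias * p * (1 - p)
  else
    p^2 * (1 + reciprocity_bias)
  p_one <- p - p_both                      # each single direction
  p_none <- 1 - 2 * p_one - p_both
  if (p_none < -1e-12)
    stop("infeasible density/reciprocity_bias combination ",
         "(reduce density or raise the bias)")
  p_none <- max(p_none, 0)

  rw <- function(k) {
    switch(weight_dist$dist,
      unif = stats::runif(k, weight_dist$min, weight_dist$max),
      exp = stats::rexp(k, weight_dist$rate),
      lnorm = stats::rlnorm(k, weight_dist$meanlog, weight_dist$sdlog),
      constant = rep(weight_dist$value, k),
      stop("unknown weight distribution: ", weight_dist$dist))
  }

  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      W <- matrix(0, n_nodes, n_nodes)
      pairs <- utils::combn(n_nodes, 2L)
      cat_draw <- sample.int(4L, ncol(pairs), replace = TRUE,
                             prob = c(p_both, p_one, p_one, p_none))
      for (q in seq_len(ncol(pairs))) {
        i <- pairs[1L, q]; j <- pairs[2L, q]
        if (cat_draw[q] == 1L) {
          W[i, j] <- rw(1L); W[j, i] <- rw(1L)
        } else if (cat_draw[q] == 2L) {
          W[i, j] <- rw(1L)
        } else if (cat_draw[q] == 3L) {
          W[j, i] <- rw(1L)
        }
      }
      W
    })
  })
  names(layers) <- paste0("L", seq_len(n_layers))
  multiplex(layers, level = level)
}
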