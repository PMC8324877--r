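#' Enumerate non-isomorphic triad patterns
#'
#' A triad pattern is a closed three-node subgraph kind — Cycle
#' (i -> j -> k -> i) or Flux (source -> middle, middle -> sink,
#' source -> sink) — together with a layer assignment for its three link
#' positions.  The pattern order is the number of distinct layers minus
#' one: order 0 keeps all links in one layer, order 1 uses two layers,
#' order 2 three.  Cycle link positions are equivalent under cyclic
#' rotation and are canonicalized (patterns identical up to rotation are
#' listed once); the three Flux positions play distinguishable roles, so
#' every assignment is its own pattern.
#'
#' For M layers the counts are: Cycle M, M(M-1), C(M,3) * 2 and Flux
#' M, 3 M(M-1), M(M-1)(M-2) for orders 0, 1, 2 — e.g. 4/4, 12/36, 8/24
#' over the four alpha layers, 2/2 and 2/6 over the two beta layers, and
#' 1/1 over the single gamma layer.
#'
#' @param layers Character vector of layer names (or a single count, in
#'   which case layers are `L1..Lm`).
#' @param order Pattern order, 0, 1 or 2.
#' @param kind `"Cycle"`, `"Flux"` or both (default).
#' @return A data frame with columns `kind`, `order`, `l1`, `l2`, `l3`
#'   (layer per link position), `name` (e.g. `"Flux ActS/ActO/TfO"`) and
#'   `sym` (the number of rotations fixing a Cycle assignment; 1 for
#'   Flux).  Empty when `order > length(layers) - 1`.
#' @export
#' @examples
#' nrow(enumerate_triad_patterns(c("ActS", "TfS", "ActO", "TfO"),
#'                               order = 1, kind = "Flux"))  # 36
enumerate_triad_patterns <- function(layers, order,
                                     kind = c("Cycle", "Flux")) {
  kind <- match.arg(kind, several.ok = TRUE)
  if (length(layers) == 1L && is.numeric(layers))
    layers <- paste0("L", seq_len(layers))
  M <- length(layers)
  stopifnot(length(order) == 1L, order %in% 0:2)
  empty <- data.frame(kind = character(), order = integer(),
                      l1 = character(), l2 = character(), l3 = character(),
                      name = character(), sym = integer(),
                      stringsAsFactors = FALSE)
  if (order > M - 1L) return(empty)

  g <- expand.grid(l1 = layers, l2 = layers, l3 = layers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ndist <- apply(g, 1L, function(r) length(unique(r)))
  g <- g[ndist == order + 1L, , drop = FALSE]

  out <- list()
  if ("Cycle" %in% kind) {
    rot <- function(v, r) v[((seq_len(3L) - 1L + r) %% 3L) + 1L]
    seen <- character(0)
    rows <- list()
    for (i in seq_len(nrow(g))) {
      v <- as.character(g[i, ])
      keys <- vapply(0:2, function(r) paste(rot(v, r), collapse = "\r"), "")
      canon <- sort(keys)[1L]
      if (canon %in% seen) next
      seen <- c(seen, canon)
      cv <- strsplit(canon, "\r", fixed = TRUE)[[1L]]
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "Cycle", order = order, l1 = cv[1L], l2 = cv[2L],
                   l3 = cv[3L], name = paste("Cycle",
                                             paste(cv, collapse = "/")),
                   sym = sum(keys == keys[1L]), stringsAsFactors = FALSE)
    }
    out <- c(out, rows)
  }
  if ("Flux" %in% kind) {
    for (i in seq_len(nrow(g))) {
      v <- as.character(g[i, ])
      out[[length(out) + 1L]] <-
        data.frame(kind = "Flux", order = order, l1 = v[1L], l2 = v[2L],
                   l3 = v[3L], name = paste("Flux",
                                            paste(v, collapse = "/")),
                   sym = 1L, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a triad pattern by intensity and coherence
#'
#' Scans all ordered node triples of the multiplex.  A pattern instance
#' exists when all three pattern links have nonzero weight in their
#' assigned layers and no link of the triad is reciprocated within the
#' union of the pattern's layers (double links are not allowed).  An
#' instance's intensity is the geometric mean of its three link weights,
#' its coherence the ratio of the geometric to the arithmetic mean
#' (always in \[0, 1\]).  The network-level intensity is the sum of
#' instance intensities (set `reduce = "mean"` for the average) and the
#' network-level coherence the mean of instance coherences.
#'
#' @param net A [multiplex()].
#' @param pattern One row of [enumerate_triad_patterns()] (or a list
#'   with elements `kind`, `l1`, `l2`, `l3` and optionally `sym`).
#' @param reduce `"sum"` (default) or `"mean"` for the network-level
#'   intensity.
#' @return A list of class `subgraph_score`: `pattern` (name),
#'   `n_instances`, `intensity`, `coherence` (`NA` when no instance
#'   exists; then intensity is 0).
#' @export
score_subgraph <- function(net, pattern, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(net, "multiplex"))
  lys <- c(pattern$l1, pattern$l2, pattern$l3)
  missing <- setdiff(unique(lys), names(net$layers))
  if (length(missing))
    stop("pattern layer(s) absent from net: ", paste(missing, collapse = ", "))
  U <- Reduce(`+`, net$layers[unique(lys)])
  sc <- triad_scan(net$layers[[lys[1L]]], net$layers[[lys[2L]]],
                   net$layers[[lys[3L]]], U,
                   identical(pattern$kind, "Cycle"))
  sym <- if (!is.null(pattern$sym)) pattern$sym else 1L
  n_inst <- sc[1L] / sym
  structure(list(
    pattern = if (!is.null(pattern$name)) pattern$name
      else paste(pattern$kind, paste(lys, collapse = "/")),
    kind = pattern$kind,
    n_instances = n_inst,
    intensity = if (reduce == "sum") sc[2L] / sym
      else if (n_inst > 0) sc[2L] / sc[1L] else 0,
    coherence = if (sc[1L] > 0) sc[3L] / sc[1L] else NA_real_),
    class = "subgraph_score")
}

#' @export
print.subgraph_score <- function(x, ...) {
  cat(sprintf("<subgraph> %s  instances %g  I = %.4g  C = %s\n", x$pattern,
              x$n_instances, x$intensity,
              if (is.na(x$coherence)) "NA" else sprintf("%.4f", x$coherence)))
  invisible(x)
}

#' Census of triad patterns over a multiplex
#'
#' Enumerates and scores every Cycle/Flux pattern of the requested
#' orders within each hierarchy level of the network (patterns never mix
#' layers across levels).
#'
#' @param net A [multiplex()].
#' @param orders Orders to include (default `0:2`).
#' @param kinds Pattern kinds (default both).
#' @param reduce Intensity reduction, see [score_subgraph()].
#' @return A data frame: `level`, `kind`, `order`, `pattern`,
#'   `n_instances`, `intensity`, `coherence`.
#' @export
triad_census <- function(net, orders = 0:2, kinds = c("Cycle", "Flux"),
                         reduce = "sum") {
  stopifnot(inherits(net, "multiplex"))
  rows <- list()
  for (lev in unique(net$level)) {
    lys <- names(net$layers)[net$level == lev]
    for (ord in orders) {
      pats <- enumerate_triad_patterns(lys, ord, kinds)
      for (i in seq_len(nrow(pats))) {
        sc <- score_subgraph(net, pats[i, ], reduce = reduce)
        rows[[length(rows) + 1L]] <-
          data.frame(level = lev, kind = pats$kind[i], order = ord,
                     pattern = sc$pattern, n_instances = sc$n_instances,
                     intensity = sc$intensity, coherence = sc$coherence,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Randomization significance of triad-pattern scores
#'
#' Upper-tail empirical p-values for the intensity and coherence of each
#' pattern against layerwise weight randomizations of the network
#' (in-strength-preserving by default), with Bonferroni-corrected flags
#' across patterns of the same kind and order.
#'
#' @param net A [multiplex()].
#' @param patterns Data frame of patterns ([enumerate_triad_patterns()]
#'   rows, possibly concatenated).
#' @param n_replicates Null replicates (default 100).
#' @param null_method `"in_strength"` (default) or `"permute"`, applied
#'   layer by layer.
#' @param seed Integer seed.
#' @param alpha Significance level for the corrected flags.
#' @param reduce Intensity reduction, see [score_subgraph()].
#' @return A data frame: pattern descriptors, observed `intensity` and
#'   `coherence`, `p_intensity`, `p_coherence`, and Bonferroni flags
#'   `sig_intensity`, `sig_coherence`.
#' @export
subgraph_significance <- function(net, patterns, n_replicates = 100L,
                                  null_method = c("in_strength", "permute"),
                                  seed = 1L, alpha = 0.05, reduce = "sum") {
  null_method <- match.arg(null_method)
  stopifnot(inherits(net, "multiplex"), n_replicates >= 1L)
  n_pat <- nrow(patterns)
  obs <- lapply(seq_len(n_pat), function(i)
    score_subgraph(net, patterns[i, ], reduce = reduce))
  null_i <- matrix(0, n_replicates, n_pat)
  null_c <- matrix(NA_real_, n_replicates, n_pat)
  with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      rnet <- net
      rnet$layers <- lapply(net$layers, randomize_weights, null_method)
      for (i in seq_len(n_pat)) {
        sc <- score_subgraph(rnet, patterns[i, ], reduce = reduce)
        null_i[rep, i] <- sc$intensity
        null_c[rep, i] <- sc$coherence
      }
    }
  })
  p_i <- vapply(seq_len(n_pat), function(i)
    (1 + sum(null_i[, i] >= obs[[i]]$intensity)) / (1 + n_replicates), 0)
  p_c <- vapply(seq_len(n_pat), function(i) {
    if (is.na(obs[[i]]$coherence)) return(NA_real_)
    nc <- null_c[, i]
    (1 + sum(!is.na(nc) & nc >= obs[[i]]$coherence)) / (1 + n_replicates)
  }, 0)
  out <- data.frame(patterns[, c("kind", "order", "l1", "l2", "l3", "name")],
                    n_instances = vapply(obs, `[[`, 0, "n_instances"),
                    intensity = vapply(obs, `[[`, 0, "intensity"),
                    coherence = vapply(obs, `[[`, 0, "coherence"),
                    p_intensity = p_i, p_coherence = p_c,
                    stringsAsFactors = FALSE)
  fam <- interaction(out$kind, out$order, drop = TRUE)
  fam_n <- stats::ave(rep(1, n_pat), fam, FUN = sum)
  out$sig_intensity <- pmin(1, out$p_intensity * fam_n) < alpha
  out$sig_coherence <- pmin(1, out$p_coherence * fam_n) < alpha
  rownames(out) <- NULL
  out
}

#' Group-level triad significance across subject networks
#'
#' The subgraph indexes are global network descriptors and are computed
#' per subject; this routine scores every pattern on each subject's
#' multiplex, draws layerwise weight randomizations per subject, and
#' compares the across-subject distribution of the real scores against
#' the pooled null scores with a one-sided (right-tail) Welch test,
#' Bonferroni corrected within each (kind, order) pattern family.
#'
#' @param nets List of [multiplex()]es (one per subject, same layers).
#' @param patterns Data frame of patterns ([enumerate_triad_patterns()]
#'   rows).
#' @param n_null Randomized replicates per subject (default 10; the
#'   pooled null has `length(nets) * n_null` entries).
#' @param null_method `"in_strength"` (default) or `"permute"`.
#' @param seed Integer seed.
#' @param alpha Significance level for the corrected flags.
#' @param reduce Intensity reduction, see [score_subgraph()].
#' @return A data frame with pattern descriptors, across-subject mean
#'   and S.D. of intensity and coherence, `p_intensity`, `p_coherence`
#'   and Bonferroni flags.
#' @export
triad_group_significance <- function(nets, patterns, n_null = 10L,
                                     null_method = c("in_strength",
                                                     "permute"),
                                     seed = 1L, alpha = 0.05,
                                     reduce = "sum") {
  null_method <- match.arg(null_method)
  stopifnot(is.list(nets), length(nets) >= 2L, n_null >= 1L)
  n_pat <- nrow(patterns)
  n_sub <- length(nets)
  score_net <- function(net) {
    sc <- lapply(seq_len(n_pat), function(i)
      score_subgraph(net, patterns[i, ], reduce = reduce))
    list(i = vapply(sc, `[[`, 0, "intensity"),
         c = vapply(sc, `[[`, 0, "coherence"))
  }
  obs <- lapply(nets, score_net)
  obs_i <- t(matrix(vapply(obs, `[[`, numeric(n_pat), "i"),
                    nrow = n_pat, ncol = n_sub))
  obs_c <- t(matrix(vapply(obs, `[[`, numeric(n_pat), "c"),
                    nrow = n_pat, ncol = n_sub))
  null_i <- matrix(0, n_sub * n_null, n_pat)
  null_c <- matrix(NA_real_, n_sub * n_null, n_pat)
  with_seed(seed, {
    r <- 0L
    for (s in seq_len(n_sub)) {
      for (q in seq_len(n_null)) {
        r <- r + 1L
        rnet <- nets[[s]]
        rnet$layers <- lapply(rnet$layers, randomize_weights, null_method)
        ns <- score_net(rnet)
        null_i[r, ] <- ns$i
        null_c[r, ] <- ns$c
      }
    }
  })
  p_one <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    welch_greater(mean(x), stats::var(x), length(x),
                  mean(y), stats::var(y), length(y))$p
  }
  out <- data.frame(patterns[, c("kind", "order", "l1", "l2", "l3", "name")],
                    intensity = colMeans(obs_i),
                    intensity_sd = apply(obs_i, 2L, stats::sd),
                    coherence = colMeans(obs_c, na.rm = TRUE),
                    coherence_sd = apply(obs_c, 2L, stats::sd, na.rm = TRUE),
                    p_intensity = vapply(seq_len(n_pat), function(i)
                      p_one(obs_i[, i], null_i[, i]), 0),
                    p_coherence = vapply(seq_len(n_pat), function(i)
                      p_one(obs_c[, i], null_c[, i]), 0),
                    stringsAsFactors = FALSE)
  fam <- interaction(out$kind, out$order, drop = TRUE)
  fam_n <- stats::ave(rep(1, n_pat), fam, FUN = sum)
  out$sig_intensity <- !is.na(out$p_intensity) &
    pmin(1, out$p_intensity * fam_n) < alpha
  out$sig_coherence <- !is.na(out$p_coherence) &
    pmin(1, out$p_coherence * fam_n) < alpha
  rownames(out) <- NULL
  out
}
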