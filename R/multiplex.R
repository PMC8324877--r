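#' Directed weighted multiplex network
#'
#' A multiplex network is an ordered set of directed weighted layers
#' over one shared node set, with no interlayer links.  Here each layer
#' is an N x N nonnegative matrix with zero diagonal; `w[i, j]` is the
#' weight of the link i -> j (row = source, column = target).  Each
#' layer carries a hierarchy tag: `"alpha"` for the four functional rule
#' layers, `"beta"` for their same/opposite-state aggregates S and O,
#' `"gamma"` for the total matrix T.
#'
#' @param layers Named list of square numeric matrices sharing
#'   dimensions (and node labels, when present).
#' @param level Character vector of hierarchy tags, one per layer
#'   (recycled); values in `"alpha"`, `"beta"`, `"gamma"`.
#' @param nodes Optional node labels; defaults to the matrices' row
#'   names or `N1..Nn`.
#' @return An object of class `multiplex`: a list with elements
#'   `layers`, `nodes`, `level`.
#' @export
multiplex <- function(layers, level = "alpha", nodes = NULL) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("layers must be a non-empty list of matrices")
  if (is.null(names(layers)))
    names(layers) <- paste0("L", seq_along(layers))
  n <- nrow(layers[[1L]])
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n)
      stop("layer ", nm, " is not a square matrix matching the node set")
    if (any(m < 0)) stop("layer ", nm, " has negative weights")
    if (any(diag(m) != 0)) stop("layer ", nm, " has self-links")
  }
  nodes <- nodes %||% rownames(layers[[1L]]) %||% paste0("N", seq_len(n))
  layers <- lapply(layers, function(m) {
    dimnames(m) <- list(nodes, nodes)
    m
  })
  level <- rep(level, length.out = length(layers))
  if (!all(level %in% c("alpha", "beta", "gamma")))
    stop("level tags must be alpha, beta or gamma")
  names(level) <- names(layers)
  structure(list(layers = layers, nodes = nodes, level = level),
            class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("<multiplex> %d nodes, %d layer(s):\n", length(x$nodes),
              length(x$layers)))
  for (nm in names(x$layers))
    cat(sprintf("  %-6s (%s)  weight %.4g  density %.3f\n", nm,
                x$level[[nm]], sum(x$layers[[nm]]),
                mean(x$layers[[nm]][offdiag(length(x$nodes))] != 0)))
  invisible(x)
}

#' Weighted aggregated overlapping adjacency matrix
#'
#' Entrywise sum of a subset of layers: the S matrix is ActS + TfS, O is
#' ActO + TfO, and the gamma-level T matrix is S + O.
#'
#' @param net A [multiplex()].
#' @param subset Character vector of layer names to sum.
#' @return A single directed weighted matrix.
#' @export
aggregate_layers <- function(net, subset) {
  stopifnot(inherits(net, "multiplex"))
  if (length(subset) == 0L) stop("subset must name at least one layer")
  missing <- setdiff(subset, names(net$layers))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  Reduce(`+`, net$layers[subset])
}

#' Extend the four rule layers to the full three-level hierarchy
#'
#' Appends the beta-level aggregates S = ActS + TfS (same-state) and
#' O = ActO + TfO (opposite-state), and the gamma-level total
#' T = S + O, to an alpha-level multiplex.
#'
#' @param net A [multiplex()] holding layers ActS, TfS, ActO, TfO.
#' @return A 7-layer `multiplex` with level tags alpha/beta/gamma.
#' @export
add_hierarchy <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  need <- c("ActS", "TfS", "ActO", "TfO")
  if (!all(need %in% names(net$layers)))
    stop("net must contain the four rule layers ActS, TfS, ActO, TfO")
  S <- aggregate_layers(net, c("ActS", "TfS"))
  O <- aggregate_layers(net, c("ActO", "TfO"))
  layers <- c(net$layers[need], list(S = S, O = O, T = S + O))
  multiplex(layers,
            level = c(rep("alpha", 4L), "beta", "beta", "gamma"),
            nodes = net$nodes)
}

#' Node strengths and overlapping degrees
#'
#' Per layer: out-strength (row sums: weight leaving the node),
#' in-strength (column sums: weight entering it) and total strength
#' (their sum).  The weighted overlapping degree of a node is its
#' strength summed across layers.
#'
#' @param net A [multiplex()].
#' @param layers Layer names over which overlapping degrees are summed
#'   (default: all layers of `net`).
#' @return A list of class `strength_vector`: `in_strength`,
#'   `out_strength`, `total_strength` (node x layer matrices) and
#'   `overlapping` (data frame with in/out/total overlapping degree).
#' @export
strengths <- function(net, layers = NULL) {
  stopifnot(inherits(net, "multiplex"))
  layers <- layers %||% names(net$layers)
  s_out <- vapply(net$layers[layers], rowSums, numeric(length(net$nodes)))
  s_in <- vapply(net$layers[layers], colSums, numeric(length(net$nodes)))
  if (length(net$nodes) == 1L) {
    s_out <- matrix(s_out, 1L); s_in <- matrix(s_in, 1L)
  }
  rownames(s_out) <- rownames(s_in) <- net$nodes
  colnames(s_out) <- colnames(s_in) <- layers
  structure(list(
    in_strength = s_in, out_strength = s_out,
    total_strength = s_in + s_out,
    overlapping = data.frame(node = net$nodes,
                             o_in = rowSums(s_in), o_out = rowSums(s_out),
                             o_total = rowSums(s_in) + rowSums(s_out),
                             row.names = NULL, stringsAsFactors = FALSE)),
    class = "strength_vector")
}

#' Per-layer total weight and connection density
#'
#' Total weight is the sum of all link weights of a layer; connection
#' density is the fraction of nonzero ordered off-diagonal entries,
#' with denominator N (N - 1) (self-links are undefined for transfer
#' entropy).  Given a list of multiplexes (e.g. per subject), the mean
#' and S.D. across subjects are reported.
#'
#' @param net A [multiplex()] or a list of multiplexes sharing layers.
#' @return A data frame with columns `layer`, `level`, `weight`,
#'   `density` (plus `weight_sd`/`density_sd` for list input).
#' @export
layer_descriptors <- function(net) {
  if (inherits(net, "multiplex")) {
    off <- offdiag(length(net$nodes))
    return(data.frame(
      layer = names(net$layers), level = unname(net$level),
      weight = vapply(net$layers, sum, 0),
      density = vapply(net$layers, function(m) mean(m[off] != 0), 0),
      row.names = NULL, stringsAsFactors = FALSE))
  }
  stopifnot(is.list(net), length(net) > 0L)
  per <- lapply(net, layer_descriptors)
  w <- vapply(per, function(d) d$weight, numeric(nrow(per[[1L]])))
  dn <- vapply(per, function(d) d$density, numeric(nrow(per[[1L]])))
  if (nrow(per[[1L]]) == 1L) { w <- matrix(w, 1L); dn <- matrix(dn, 1L) }
  data.frame(layer = per[[1L]]$layer, level = per[[1L]]$level,
             weight = rowMeans(w), weight_sd = apply(w, 1L, stats::sd),
             density = rowMeans(dn), density_sd = apply(dn, 1L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a multiplex network as a directory bundle
#'
#' One tab-delimited square table per layer plus a JSON manifest with
#' layer names, hierarchy tags and node labels.
#'
#' @param net A [multiplex()].
#' @param dir Directory path (created if missing).
#' @return `read_multiplex` returns the reconstructed `multiplex`.
#' @export
write_multiplex <- function(net, dir) {
  stopifnot(inherits(net, "multiplex"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(paste0("layer-", names(net$layers), ".tsv"),
                           names(net$layers))
  for (nm in names(net$layers)) {
    df <- data.frame(node = net$nodes, net$layers[[nm]],
                     check.names = FALSE)
    colnames(df) <- c("node", net$nodes)
    utils::write.table(df, file.path(dir, files[[nm]]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(layers = as.list(files),
                   level = as.list(net$level), nodes = net$nodes)
  jsonlite::write_json(manifest, file.path(dir, "multiplex.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_multiplex
#' @export
read_multiplex <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "multiplex.json"),
                                  simplifyVector = TRUE)
  layers <- lapply(manifest$layers, function(f) {
    df <- utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                            check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  })
  multiplex(layers, level = unlist(manifest$level),
            nodes = manifest$nodes)
}
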