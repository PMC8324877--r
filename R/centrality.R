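#' Central nodes and multiplex centrality classes
#'
#' A node is central in a layer, for a given strength kind (in, out or
#' total), when its strength lies strictly above the layer's third
#' quartile (75th percentile, linear-interpolation quantile convention).
#' Across the layers of one hierarchy level the presence fraction f of
#' a node (fraction of layers in which it is central) classifies it as
#' a local central node (f <= 0.25), an intermediate multiplex central
#' node (0.25 < f <= 0.75) or a multiplex central node (f > 0.75);
#' nodes central nowhere are unclassified (`"none"`).
#'
#' @param net A [multiplex()].
#' @param level Restrict to the layers of one hierarchy level (default:
#'   all layers of `net`).
#' @return A list of class `central_node_report`: `central` (data frame
#'   layer x kind x node logical flags, long format), `classes` (data
#'   frame node x kind with presence fraction and class), `q3` (layer x
#'   kind third-quartile thresholds).
#' @export
central_nodes <- function(net, level = NULL) {
  stopifnot(inherits(net, "multiplex"))
  lys <- if (is.null(level)) names(net$layers)
    else names(net$layers)[net$level == level]
  if (length(lys) == 0L) stop("no layers at the requested level")
  st <- strengths(net, layers = lys)
  kinds <- c(in_ = "in_strength", out = "out_strength",
             total = "total_strength")
  central <- list()
  q3 <- matrix(NA_real_, length(lys), length(kinds),
               dimnames = list(lys, names(kinds)))
  flag <- array(FALSE, c(length(net$nodes), length(lys), length(kinds)),
                dimnames = list(net$nodes, lys, names(kinds)))
  for (kn in seq_along(kinds)) {
    sm <- st[[kinds[kn]]]
    for (ly in seq_along(lys)) {
      q <- stats::quantile(sm[, lys[ly]], 0.75, type = 7, names = FALSE)
      q3[ly, kn] <- q
      flag[, ly, kn] <- sm[, lys[ly]] > q
      hit <- net$nodes[flag[, ly, kn]]
      if (length(hit))
        central[[length(central) + 1L]] <- data.frame(
          layer = lys[ly], kind = names(kinds)[kn], node = hit,
          stringsAsFactors = FALSE)
    }
  }
  classes <- do.call(rbind, lapply(names(kinds), function(kn) {
    f <- rowMeans(flag[, , kn, drop = FALSE][, , 1L, drop = FALSE])
    cls <- ifelse(f == 0, "none",
           ifelse(f <= 0.25, "local",
           ifelse(f <= 0.75, "intermediate", "multiplex")))
    data.frame(node = net$nodes, kind = kn, presence = unname(f),
               class = unname(cls), stringsAsFactors = FALSE)
  }))
  central <- if (length(central)) do.call(rbind, central)
    else data.frame(layer = character(), kind = character(),
                    node = character(), stringsAsFactors = FALSE)
  structure(list(central = central, classes = classes,
                 q3 = q3, layers = lys),
            class = "central_node_report")
}

#' @export
print.central_node_report <- function(x, ...) {
  cat(sprintf("<central_nodes> %d layer(s); %d central flags\n",
              length(x$layers), nrow(x$central)))
  invisible(x)
}

#' Classify a presence fraction into a multiplex centrality class
#'
#' Boundary conventions: local when `0 < f <= 0.25`, intermediate when
#' `0.25 < f <= 0.75`, multiplex when `f > 0.75`; `f = 0` is `"none"`.
#'
#' @param f Presence fraction(s) in \[0, 1\].
#' @return Character vector of classes.
#' @export
centrality_class <- function(f) {
  stopifnot(all(f >= 0 & f <= 1))
  ifelse(f == 0, "none",
  ifelse(f <= 0.25, "local",
  ifelse(f <= 0.75, "intermediate", "multiplex")))
}
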