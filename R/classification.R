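#' Correlation between rules' link-weight profiles
#'
#' Pearson correlation between the vectorized subject-mean link-weight
#' matrices of the selected rules: for each rule the tensor is averaged
#' over subjects at the chosen threshold and flattened over the ordered
#' off-diagonal pairs; rules whose profiles co-vary across links are
#' candidates for the same functional class.
#'
#' @param tensor A [build_rule_tensor()] result.
#' @param rules Selected rule set (data frame with `a`,`b`,`bnext`
#'   columns, list of [rule_spec()]s, or canonical indices); >= 2 rules.
#' @param threshold Index of the threshold level to use (default: the
#'   highest).
#' @return A symmetric rule x rule correlation matrix with unit
#'   diagonal; a zero-variance profile yields `NA` entries.
#' @export
rule_correlation <- function(tensor, rules, threshold = NULL) {
  stopifnot(inherits(tensor, "rule_tensor"))
  idx <- as_rule_indices(rules)
  if (length(idx) < 2L) stop("need at least two rules")
  d <- dim(tensor)
  t_use <- threshold %||% d[5L]
  off <- offdiag(d[2L])
  prof <- vapply(idx, function(k) {
    m <- apply(tensor[, , , k, t_use, drop = FALSE], c(2L, 3L), mean)
    m[off]
  }, numeric(sum(off)))
  colnames(prof) <- all_rules()$id[idx]
  sds <- apply(prof, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(prof))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- ifelse(sds == 0, NA_real_, 1)
  cm
}

#' Hierarchical clustering of rules
#'
#' Agglomerative clustering (average linkage) of the rules on the
#' distance 1 - r, where r is the Pearson correlation between the rules'
#' link profiles, returning the dendrogram with its 2- and 4-cluster
#' cuts.  Sign-symmetric rule pairs cluster together first; the 2-cut
#' recovers the same-state versus opposite-state groups.
#'
#' @param corr Correlation matrix from [rule_correlation()].
#' @return A list with `hclust`, `cut2` and `cut4` (named membership
#'   vectors).
#' @export
cluster_rules <- function(corr) {
  if (anyNA(corr)) {
    bad <- unique(c(rownames(corr)[apply(is.na(corr), 1L, any)]))
    stop("undefined correlations involving rule(s): ",
         paste(bad, collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  n <- nrow(corr)
  list(hclust = hc,
       cut2 = stats::cutree(hc, k = min(2L, n)),
       cut4 = stats::cutree(hc, k = min(4L, n)))
}

#' Assemble the four functional rule layers
#'
#' Builds the ActS, ActO, TfS and TfO directed weighted matrices: the
#' layer weight for an ordered pair (i, j) is the sum of the local-TE
#' values of the label's two sign-symmetric rules at the chosen
#' threshold.  These four matrices are the alpha-hierarchical layers of
#' the multiplex network.
#'
#' @param tensor A [build_rule_tensor()] result.
#' @param threshold Index of the threshold level (default: the highest,
#'   where the selection statistics are anchored).
#' @param subject_reduction `"mean"` (default) for the across-subject
#'   mean layers, `"per-subject"` for one multiplex per subject.
#' @return A [multiplex()] with layers ActS, TfS, ActO, TfO (level
#'   `"alpha"`), or a list of such multiplexes (one per subject).
#' @export
build_rule_layers <- function(tensor, threshold = NULL,
                              subject_reduction = c("mean", "per-subject")) {
  stopifnot(inherits(tensor, "rule_tensor"))
  subject_reduction <- match.arg(subject_reduction)
  d <- dim(tensor)
  t_use <- threshold %||% d[5L]
  tax <- rule_taxonomy()
  labels <- c("ActS", "TfS", "ActO", "TfO")

  one_subject <- function(s) {
    layers <- lapply(labels, function(lb) {
      ki <- tax$index[tax$label == lb]
      m <- tensor[s, , , ki[1L], t_use] + tensor[s, , , ki[2L], t_use]
      dimnames(m) <- dimnames(tensor)[c(2L, 3L)]
      m
    })
    names(layers) <- labels
    multiplex(layers, level = stats::setNames(rep("alpha", 4L), labels))
  }

  if (subject_reduction == "per-subject") {
    out <- lapply(seq_len(d[1L]), one_subject)
    names(out) <- dimnames(tensor)[[1L]]
    return(out)
  }
  layers <- lapply(labels, function(lb) {
    ki <- tax$index[tax$label == lb]
    m <- apply(tensor[, , , ki[1L], t_use, drop = FALSE], c(2L, 3L), mean) +
      apply(tensor[, , , ki[2L], t_use, drop = FALSE], c(2L, 3L), mean)
    dimnames(m) <- dimnames(tensor)[c(2L, 3L)]
    m
  })
  names(layers) <- labels
  multiplex(layers, level = stats::setNames(rep("alpha", 4L), labels))
}
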