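#' The 27 state-triple interaction rules
#'
#' An interaction rule is an ordered triple (aState, bState, bNextState),
#' each state in \{-1, 0, 1\}: the source region A is in `aState` and the
#' target region B in `bState` at time step n, and B moves to `bNextState`
#' at step n + 1.  With three states and three slots there are exactly
#' 3^3 = 27 rules; each indexes one summand of the pairwise transfer
#' entropy between A and B.
#'
#' @return A data frame with 27 rows and columns `a`, `b`, `bnext`
#'   (integer states), `id` (compact string such as `"1,0>1"`) and `index`
#'   (the canonical 1..27 position, equal to
#'   `9*(a+1) + 3*(b+1) + (bnext+1) + 1`).
#' @seealso [rule_spec()], [rule_index()], [label_rules()]
#' @export
#' @examples
#' nrow(all_rules())  # 27
all_rules <- function() {
  g <- expand.grid(bnext = -1:1, b = -1:1, a = -1:1,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("a", "b", "bnext")]
  g <- g[order(9 * (g$a + 1) + 3 * (g$b + 1) + (g$bnext + 1)), ]
  rownames(g) <- NULL
  g$id <- rule_id(g$a, g$b, g$bnext)
  g$index <- seq_len(27L)
  g
}

#' Construct a single rule triple
#'
#' @param a,b,bnext States in \{-1, 0, 1\}: source state at n, target state
#'   at n, target state at n + 1.
#' @return A named integer vector of class `rule_spec` with elements
#'   `a`, `b`, `bnext`.
#' @export
#' @examples
#' rule_spec(1, 0, 1)   # the ActS "activate to same state" rule
rule_spec <- function(a, b, bnext) {
  st <- c(a = as.integer(a), b = as.integer(b), bnext = as.integer(bnext))
  if (!all(st %in% -1:1))
    stop("rule states must lie in {-1, 0, 1}")
  structure(st, class = "rule_spec")
}

#' @export
print.rule_spec <- function(x, ...) {
  cat(sprintf("<rule> A(%d) + B(%d) -> B'(%d)\n", x[["a"]], x[["b"]],
              x[["bnext"]]))
  invisible(x)
}

#' Canonical 1..27 index of a rule
#'
#' @param rule A `rule_spec`, or anything coercible to a length-3 integer
#'   vector (a, b, bnext).
#' @return Integer scalar in 1..27.
#' @export
rule_index <- function(rule) {
  r <- as.integer(rule)
  if (length(r) != 3L || !all(r %in% -1:1))
    stop("a rule is a triple of states in {-1, 0, 1}")
  9L * (r[1L] + 1L) + 3L * (r[2L] + 1L) + (r[3L] + 1L) + 1L
}

rule_id <- function(a, b, bnext) sprintf("%d,%d>%d", a, b, bnext)

#' Functional taxonomy of the eight core rules
#'
#' The eight rules surviving selection organize into four functional
#' classes, two sign-symmetric rules each:
#' \describe{
#'   \item{ActS}{(de-)activates B to the same state as A:
#'     (1,0>1), (-1,0>-1)}
#'   \item{ActO}{(de-)activates B to the opposite state of A:
#'     (1,0>-1), (-1,0>1)}
#'   \item{TfS}{turns B off when A and B are in opposite states:
#'     (1,-1>0), (-1,1>0)}
#'   \item{TfO}{turns B off when A and B are in the same state:
#'     (1,1>0), (-1,-1>0)}
#' }
#' ActS/TfS drive the node pair towards the same state (group G1,
#' positive-connectivity-like); ActO/TfO towards opposite states (group
#' G2, negative-connectivity-like).
#'
#' @return A data frame with columns `a`, `b`, `bnext`, `id`, `index`,
#'   `label` (ActS/ActO/TfS/TfO) and `group` (G1/G2).
#' @export
rule_taxonomy <- function() {
  tab <- rbind(
    c(1, 0, 1, "ActS", "G1"), c(-1, 0, -1, "ActS", "G1"),
    c(1, 0, -1, "ActO", "G2"), c(-1, 0, 1, "ActO", "G2"),
    c(1, -1, 0, "TfS", "G1"), c(-1, 1, 0, "TfS", "G1"),
    c(1, 1, 0, "TfO", "G2"), c(-1, -1, 0, "TfO", "G2"))
  out <- data.frame(a = as.integer(tab[, 1]), b = as.integer(tab[, 2]),
                    bnext = as.integer(tab[, 3]),
                    label = tab[, 4], group = tab[, 5],
                    stringsAsFactors = FALSE)
  out$id <- rule_id(out$a, out$b, out$bnext)
  out$index <- mapply(function(a, b, c) rule_index(c(a, b, c)),
                      out$a, out$b, out$bnext)
  out[, c("a", "b", "bnext", "id", "index", "label", "group")]
}

#' Label rules with their functional class
#'
#' Maps each rule of a selected set to its class in the fixed taxonomy
#' (ActS, ActO, TfS, TfO).  Only the eight core rules carry a label;
#' any other rule is an error.
#'
#' @param rules A list of `rule_spec`s, a data frame with columns
#'   `a`, `b`, `bnext`, or an integer vector of canonical rule indices.
#' @return A data frame (subset of [rule_taxonomy()] rows, in input
#'   order).
#' @export
#' @examples
#' label_rules(list(rule_spec(1, 0, 1)))$label  # "ActS"
label_rules <- function(rules) {
  idx <- as_rule_indices(rules)
  tax <- rule_taxonomy()
  pos <- match(idx, tax$index)
  if (anyNA(pos)) {
    bad <- all_rules()$id[idx[is.na(pos)]]
    stop("rule(s) outside the eight labelled core rules: ",
         paste(bad, collapse = ", "))
  }
  out <- tax[pos, ]
  rownames(out) <- NULL
  out
}

# Coerce the accepted rule-set representations to canonical indices.
as_rule_indices <- function(rules) {
  if (is.data.frame(rules))
    return(vapply(seq_len(nrow(rules)), function(i)
      rule_index(c(rules$a[i], rules$b[i], rules$bnext[i])), 1L))
  if (is.list(rules))
    return(vapply(rules, rule_index, 1L))
  idx <- as.integer(rules)
  if (!all(idx %in% 1:27)) stop("rule indices must lie in 1..27")
  idx
}
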