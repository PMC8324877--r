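#' Local transfer entropy of one interaction rule
#'
#' For ternary sequences a (source) and b (target), the transfer entropy
#' from A to B with one-step histories (k = l = 1) decomposes into 27
#' summands, one per state triple (A_n, B_n, B_n+1).  This function
#' returns the plug-in estimate of a single summand,
#' \deqn{\hat p(B_{n+1}, A_n, B_n)\,
#'       \ln\frac{\hat p(B_{n+1} \mid A_n, B_n)}
#'               {\hat p(B_{n+1} \mid B_n)},}
#' with frequencies taken over the n = 1..T-1 transitions.  A negative
#' value is clamped to 0 (read as misinformation transfer), and a rule
#' whose antecedent pair never occurs contributes exactly 0.
#'
#' @param a,b Integer vectors over \{-1, 0, 1\} of equal length >= 3.
#' @param rule A [rule_spec()] (or length-3 state vector).
#' @param clamp Clamp negative contributions to zero (default `TRUE`).
#' @return Nonnegative scalar (may be negative when `clamp = FALSE`),
#'   in nats.
#' @export
#' @examples
#' a <- c(1, 0, 1, 1, 0, 0, 1)
#' b <- c(0, 1, 0, 0, 1, 0, 0)
#' rule_local_te(a, b, rule_spec(1, 0, 1))
rule_local_te <- function(a, b, rule, clamp = TRUE) {
  if (length(a) != length(b)) stop("sequences must have the same length")
  if (length(a) < 3L) stop("sequences must have length >= 3")
  S <- rbind(as.integer(a), as.integer(b))
  te <- rule_te_matrix(ternary_series(S), clamp = clamp)
  te[1L, 2L, rule_index(rule)]
}

#' Pairwise transfer entropy of ternary sequences
#'
#' Plug-in (maximum-likelihood) transfer entropy from `a` to `b` with
#' k = l = 1 histories, i.e. the sum of all 27 unclamped rule
#' contributions.
#'
#' @inheritParams rule_local_te
#' @return Scalar transfer entropy in nats.
#' @export
transfer_entropy <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have the same length")
  if (length(a) < 3L) stop("sequences must have length >= 3")
  S <- rbind(as.integer(a), as.integer(b))
  te <- rule_te_matrix(ternary_series(S), clamp = FALSE)
  sum(te[1L, 2L, ])
}

# All-pairs, all-rules local TE for one ternary matrix.
#
# S: regions x time over {-1,0,1} (ternary_series or plain matrix).
# Returns an R x R x 27 array; [i, j, r] is the contribution of rule r
# to the transfer entropy from region i (source) to region j (target).
# Diagonal entries are structurally zero.  Transitions flagged FALSE in
# the series' `transition_ok` attribute are excluded from all counts.
#
# The counting is done with 27 indicator cross-products, so the cost is
# a handful of R x T by T x R matrix multiplications.
rule_te_matrix <- function(S, clamp = TRUE) {
  ok <- attr(S, "transition_ok")
  S <- unclass(S)
  storage.mode(S) <- "integer"
  R <- nrow(S)
  Tt <- ncol(S)
  if (Tt < 3L) stop("need at least 3 time points")
  X <- S[, -Tt, drop = FALSE]
  Y <- S[, -1L, drop = FALSE]
  if (!is.null(ok)) {
    X <- X[, ok, drop = FALSE]
    Y <- Y[, ok, drop = FALSE]
  }
  n_tr <- ncol(X)
  if (n_tr < 1L) stop("no valid transitions")

  a_ind <- lapply(-1:1, function(s) (X == s) * 1)
  pc <- 3L * (X + 1L) + (Y + 1L)          # target (B_n, B_n+1) code 0..8
  b_ind <- lapply(0:8, function(cc) (pc == cc) * 1)

  cnt <- array(0, c(R, R, 27L))
  for (s in 0:2)
    for (cc in 0:8)
      cnt[, , 9L * s + cc + 1L] <- tcrossprod(a_ind[[s + 1L]],
                                              b_ind[[cc + 1L]])

  nbc <- vapply(b_ind, rowSums, numeric(R))        # R x 9: #(B_n=b, B_n+1=c)
  if (R == 1L) nbc <- matrix(nbc, nrow = 1L)
  nb <- vapply(0:2, function(bb)
    rowSums(nbc[, 3L * bb + 1:3, drop = FALSE]), numeric(R))  # R x 3

  te <- array(0, c(R, R, 27L))
  for (s in 0:2) {
    for (bb in 0:2) {
      nab <- cnt[, , 9L * s + 3L * bb + 1L] +
        cnt[, , 9L * s + 3L * bb + 2L] +
        cnt[, , 9L * s + 3L * bb + 3L]
      for (cc in 0:2) {
        k <- 9L * s + 3L * bb + cc + 1L
        C <- cnt[, , k]
        num <- C * rep(nb[, bb + 1L], each = R)
        den <- nab * rep(nbc[, 3L * bb + cc + 1L], each = R)
        val <- matrix(0, R, R)
        pos <- C > 0
        val[pos] <- (C[pos] / n_tr) * log(num[pos] / den[pos])
        te[, , k] <- val
      }
    }
  }
  for (k in 1:27) {
    d <- te[, , k]
    diag(d) <- 0
    te[, , k] <- d
  }
  if (clamp) te[te < 0] <- 0
  lab <- rownames(S) %||% paste0("R", seq_len(R))
  dimnames(te) <- list(source = lab, target = lab, rule = all_rules()$id)
  te
}

#' Build the subject x pair x rule x threshold local-TE tensor
#'
#' Applies the rule-resolved local TE to every ordered region pair, for
#' every subject and discretization threshold.  Continuous input is
#' z-scored ([zscore_rows()]) and ternarized ([discretize()]) at each
#' threshold; ternary input ([ternary_series()]) is used as is, on a
#' single threshold level.
#'
#' @param subjects A list, one element per subject: either a continuous
#'   regions x time numeric matrix or a `ternary_series`.  All subjects
#'   must share region count and labels.
#' @param thresholds Increasing positive S.D. thresholds (default
#'   `c(0.25, 0.5, 0.75, 1)`); ignored for ternary input.
#' @param clamp Clamp negative contributions to zero (default `TRUE`).
#' @return A 5-d array of class `rule_tensor` with dimensions
#'   subject x source x target x rule x threshold and dimnames; the
#'   diagonal (source = target) is structurally zero.  History lengths
#'   are k = l = 1.
#' @export
build_rule_tensor <- function(subjects, thresholds = c(0.25, 0.5, 0.75, 1),
                              clamp = TRUE) {
  if (!is.list(subjects)) subjects <- list(subjects)
  n_sub <- length(subjects)
  if (n_sub == 0L) stop("no subjects")
  ternary_in <- inherits(subjects[[1L]], "ternary_series")
  labs <- lapply(subjects, function(s)
    rownames(s) %||% paste0("R", seq_len(nrow(s))))
  if (length(unique(vapply(labs, paste, "", collapse = "\r"))) != 1L)
    stop("subjects differ in region count or labels")
  lab <- labs[[1L]]
  R <- length(lab)
  if (ternary_in) {
    thr0 <- attr(subjects[[1L]], "threshold")
    thresholds <- if (is.null(thr0) || is.na(thr0)) NA_real_ else thr0
  } else {
    if (any(diff(thresholds) <= 0) || any(thresholds <= 0))
      stop("thresholds must be positive and strictly increasing")
  }
  n_thr <- length(thresholds)
  sub_names <- names(subjects) %||% paste0("S", seq_len(n_sub))

  vals <- array(0, c(n_sub, R, R, 27L, n_thr),
                dimnames = list(subject = sub_names, source = lab,
                                target = lab, rule = all_rules()$id,
                                threshold = format(thresholds)))
  for (s in seq_len(n_sub)) {
    if (ternary_in) {
      vals[s, , , , 1L] <- rule_te_matrix(subjects[[s]], clamp = clamp)
    } else {
      z <- zscore_rows(subjects[[s]])
      ok <- attr(subjects[[s]], "transition_ok")
      for (t in seq_len(n_thr)) {
        ts <- discretize(z, thresholds[t])
        if (!is.null(ok)) attr(ts, "transition_ok") <- ok
        vals[s, , , , t] <- rule_te_matrix(ts, clamp = clamp)
      }
    }
  }
  structure(vals, thresholds = thresholds, history_k = 1L, history_l = 1L,
            class = c("rule_tensor", "array"))
}

#' @export
print.rule_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(paste0("<rule_tensor> %d subject(s) x %d x %d regions x ",
                     "%d rules x %d threshold(s)\n"),
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}
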