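#' Threshold trends of the rule-resolved local TE
#'
#' For each rule: the total local TE per threshold (summed over subjects
#' and ordered pairs), the mean squared error per threshold (mean squared
#' deviation of the subject-level sums from their across-subject mean),
#' and flags marking a strictly increasing trend of either quantity
#' across the ordered thresholds.  Core rules express more strongly as
#' the event threshold sharpens, so a jointly increasing TE and MSE
#' trend is the first screening feature of the selection procedure.
#'
#' @param tensor A [build_rule_tensor()] result with >= 2 thresholds
#'   (flags are `NA` with a single threshold).
#' @return A list with `totals` (rule x threshold), `mse`
#'   (rule x threshold), `subject_sums` (subject x rule x threshold) and
#'   a data frame `flags` with per-rule `increasing_te`/`increasing_mse`.
#' @export
rule_trend_stats <- function(tensor) {
  stopifnot(inherits(tensor, "rule_tensor"))
  d <- dim(tensor)
  n_sub <- d[1L]; R <- d[2L]; n_thr <- d[5L]
  off <- offdiag(R)
  subject_sums <- array(0, c(n_sub, 27L, n_thr),
                        dimnames = dimnames(tensor)[c(1L, 4L, 5L)])
  for (s in seq_len(n_sub))
    for (t in seq_len(n_thr))
      for (k in 1:27)
        subject_sums[s, k, t] <- sum(tensor[s, , , k, t][off])
  totals <- apply(subject_sums, c(2L, 3L), sum)
  mse <- apply(subject_sums, c(2L, 3L), function(v) mean((v - mean(v))^2))
  strictly_up <- function(v) if (length(v) < 2L) NA else all(diff(v) > 0)
  flags <- data.frame(rule = all_rules()$id,
                      increasing_te = apply(totals, 1L, strictly_up),
                      increasing_mse = apply(mse, 1L, strictly_up),
                      stringsAsFactors = FALSE)
  list(totals = totals, mse = mse, subject_sums = subject_sums,
       flags = flags)
}

#' Select significant interaction rules against the reshuffling null
#'
#' Screens the 27 rules at the highest threshold of the tensor:
#' \enumerate{
#'   \item a group-level one-sided (right-tail) Welch test of the
#'     subject-level real sums against the null-ensemble sums, Bonferroni
#'     corrected across the 27 rules tested;
#'   \item per-subject one-sided Welch tests of the subject's pair-level
#'     values against the pooled null pair statistics, Bonferroni
#'     corrected across all per-subject tests performed (27 rules x
#'     subjects), yielding the fraction of subjects significant per rule;
#'   \item a rule is selected when the group test passes and the trend
#'     requirement holds (`trend = "both"`: both the increasing-TE and
#'     the increasing-MSE flag; `"any"`: at least one; `"none"`: trends
#'     not required).
#' }
#' When a test degenerates (zero variance in both samples) the decision
#' falls back to a direct location comparison and is recorded.
#'
#' @param tensor A [build_rule_tensor()] result.
#' @param null A [reshuffle_null()] ensemble evaluated at the tensor's
#'   highest threshold.
#' @param alpha Family-wise significance level (default 0.05).
#' @param trend Trend requirement, see above (default `"both"`).
#' @return A list of class `rule_selection` with elements `selected`
#'   (data frame of selected rules), `group` (per-rule group-test table),
#'   `subject_table` (per-rule fraction of significant subjects),
#'   `per_subject` (logical subject x rule matrix), `excluded_subjects`
#'   (subjects with no significant selected rule), `n_tests`, `alpha`.
#' @export
rule_selection <- function(tensor, null, alpha = 0.05,
                           trend = c("both", "any", "none")) {
  trend <- match.arg(trend)
  stopifnot(inherits(tensor, "rule_tensor"), inherits(null, "null_ensemble"))
  d <- dim(tensor)
  n_sub <- d[1L]; R <- d[2L]; n_thr <- d[5L]
  off <- offdiag(R)
  stats <- rule_trend_stats(tensor)
  # anchor at the highest threshold; the null's matching (last) level
  t_hi <- n_thr
  nt_hi <- dim(null$sums)[4L]

  real_sums <- stats$subject_sums[, , t_hi, drop = FALSE][, , 1L]
  if (n_sub == 1L) real_sums <- matrix(real_sums, nrow = 1L)

  group <- data.frame(rule = all_rules()$id, p = NA_real_,
                      degenerate = FALSE, stringsAsFactors = FALSE)
  for (k in 1:27) {
    x <- real_sums[, k]
    y <- as.vector(null$sums[, , k, nt_hi])
    w <- welch_greater(mean(x), stats::var(x), length(x),
                       mean(y), stats::var(y), length(y))
    group$p[k] <- w$p
    group$degenerate[k] <- w$degenerate
  }
  group$p_bonf <- pmin(1, group$p * 27)
  group$significant <- group$p_bonf < alpha

  # per-subject pair-level tests
  per_subject <- matrix(FALSE, n_sub, 27L,
                        dimnames = dimnames(tensor)[c(1L, 4L)])
  n_tests <- n_sub * 27L
  for (s in seq_len(n_sub)) {
    for (k in 1:27) {
      v <- tensor[s, , , k, t_hi][off]
      w <- welch_greater(mean(v), stats::var(v), length(v),
                         null$pair_mean[s, k, nt_hi],
                         null$pair_var[s, k, nt_hi], null$pair_n)
      per_subject[s, k] <- pmin(1, w$p * n_tests) < alpha
    }
  }
  subject_table <- data.frame(rule = all_rules()$id,
                              fraction_significant = colMeans(per_subject),
                              stringsAsFactors = FALSE)

  trend_ok <- switch(trend,
    both = stats$flags$increasing_te & stats$flags$increasing_mse,
    any = stats$flags$increasing_te | stats$flags$increasing_mse,
    none = rep(TRUE, 27L))
  trend_ok[is.na(trend_ok)] <- switch(trend, none = TRUE, FALSE)
  sel_idx <- which(group$significant & trend_ok)
  selected <- all_rules()[sel_idx, , drop = FALSE]
  rownames(selected) <- NULL

  excluded <- if (length(sel_idx))
    rownames(per_subject)[rowSums(per_subject[, sel_idx, drop = FALSE]) == 0]
  else character(0)

  structure(list(selected = selected, group = group,
                 subject_table = subject_table, per_subject = per_subject,
                 excluded_subjects = excluded, n_tests = n_tests,
                 alpha = alpha, trend = trend, trend_stats = stats),
            class = "rule_selection")
}

#' @export
print.rule_selection <- function(x, ...) {
  cat(sprintf("<rule_selection> %d rule(s) selected at alpha = %g (trend: %s)\n",
              nrow(x$selected), x$alpha, x$trend))
  if (nrow(x$selected)) cat("  ", paste(x$selected$id, collapse = "  "), "\n")
  invisible(x)
}
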