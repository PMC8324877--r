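#' Time-reshuffling null ensemble for the rule tensor
#'
#' Each replicate permutes every region's time order independently (a
#' uniform permutation per region, drawn fresh per threshold and
#' replicate) and recomputes the local-TE tensor.  Because only the time
#' sequence is randomized, the marginal state frequencies of every
#' region are preserved exactly, while all temporal dependence — and
#' hence all information transfer — is destroyed.
#'
#' For large problems the full replicate tensor is prohibitive to keep,
#' so the ensemble always stores the sufficient statistics used by the
#' selection tests (per subject/rule/threshold: replicate sums over
#' pairs, and pooled pair-level mean/variance/count), and keeps the full
#' replicate values only when small enough (or when `keep_values =
#' TRUE`).
#'
#' @param subjects As in [build_rule_tensor()]: list of continuous
#'   matrices or `ternary_series`, one per subject.
#' @param n_replicates Number of reshuffling replicates (default 100).
#' @param seed Integer seed; the ensemble is reproducible given the seed.
#' @param thresholds Thresholds at which to evaluate the null (default:
#'   1, the highest level of the reference sweep, where the selection
#'   statistics are anchored); ignored for ternary input.
#' @param keep_values Force keeping (`TRUE`) or dropping (`FALSE`) the
#'   full replicate x subject x source x target x rule x threshold
#'   array; default keeps it when it has at most 2e7 entries.
#' @return A list of class `null_ensemble` with elements `sums`
#'   (replicate x subject x rule x threshold array of pair sums),
#'   `pair_mean`, `pair_var`, `pair_n` (subject x rule x threshold),
#'   `n_replicates`, `thresholds`, and optionally `values`.
#' @export
reshuffle_null <- function(subjects, n_replicates = 100L, seed = 1L,
                           thresholds = 1, keep_values = NULL) {
  if (!is.list(subjects)) subjects <- list(subjects)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  n_sub <- length(subjects)
  ternary_in <- inherits(subjects[[1L]], "ternary_series")
  R <- nrow(subjects[[1L]])
  if (ternary_in) thresholds <- attr(subjects[[1L]], "threshold") %||% NA_real_
  n_thr <- length(thresholds)
  if (is.null(keep_values))
    keep_values <- n_replicates * n_sub * R * R * 27 * n_thr <= 2e7

  sub_names <- names(subjects) %||% paste0("S", seq_len(n_sub))
  sums <- array(0, c(n_replicates, n_sub, 27L, n_thr),
                dimnames = list(NULL, subject = sub_names,
                                rule = all_rules()$id,
                                threshold = format(thresholds)))
  acc_s <- array(0, c(n_sub, 27L, n_thr))
  acc_s2 <- array(0, c(n_sub, 27L, n_thr))
  vals <- if (keep_values)
    array(0, c(n_replicates, n_sub, R, R, 27L, n_thr)) else NULL

  off <- offdiag(R)
  # pre-ternarize continuous subjects once per threshold: permuting the
  # states is equivalent to permuting the raw signal (z-scoring is
  # permutation-invariant)
  tern <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    if (ternary_in) {
      tern[[s]] <- list(subjects[[s]])
    } else {
      z <- zscore_rows(subjects[[s]])
      tern[[s]] <- lapply(thresholds, function(th) discretize(z, th))
    }
  }

  with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      for (s in seq_len(n_sub)) {
        for (t in seq_len(n_thr)) {
          ts0 <- tern[[s]][[t]]
          Tt <- ncol(ts0)
          perm <- t(vapply(seq_len(R), function(i) sample.int(Tt),
                           integer(Tt)))
          shuf <- unclass(ts0)
          for (i in seq_len(R)) shuf[i, ] <- shuf[i, perm[i, ]]
          te <- rule_te_matrix(ternary_series(shuf))
          for (k in 1:27) {
            m <- te[, , k]
            v <- m[off]
            sums[rep, s, k, t] <- sum(v)
            acc_s[s, k, t] <- acc_s[s, k, t] + sum(v)
            acc_s2[s, k, t] <- acc_s2[s, k, t] + sum(v * v)
          }
          if (keep_values) vals[rep, s, , , , t] <- te
        }
      }
    }
  })

  n_pair <- sum(off) * n_replicates
  pair_mean <- acc_s / n_pair
  pair_var <- (acc_s2 - n_pair * pair_mean^2) / (n_pair - 1)
  pair_var[pair_var < 0] <- 0
  dimnames(pair_mean) <- dimnames(pair_var) <-
    list(subject = sub_names, rule = all_rules()$id,
         threshold = format(thresholds))

  structure(list(sums = sums, pair_mean = pair_mean, pair_var = pair_var,
                 pair_n = n_pair, n_replicates = n_replicates,
                 thresholds = thresholds, values = vals),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d replicates, %d subject(s), %d threshold(s)%s\n",
              x$n_replicates, dim(x$sums)[2], length(x$thresholds),
              if (is.null(x$values)) " (summary statistics only)" else ""))
  invisible(x)
}
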