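#' Ternary event series
#'
#' A `ternary_series` is a regions x time integer matrix over
#' \{-1, 0, 1\} — activation, null-activation, deactivation events — with
#' region labels as row names and the discretization threshold (in S.D.
#' units) kept as an attribute.  An optional logical attribute
#' `transition_ok` (length `ncol - 1`) marks which consecutive-step
#' transitions may be counted; splicing out scrubbed scans sets it to
#' `FALSE` across the splice so that artificial transitions never enter
#' the transfer-entropy counts.
#'
#' @param states Integer matrix over \{-1, 0, 1\}, rows = regions.
#' @param region_labels Optional character vector of region short names;
#'   defaults to existing row names or `R1..Rn`.
#' @param threshold The S.D. fraction used for discretization (or `NA`
#'   for series generated directly in state space).
#' @param transition_ok Optional logical vector, length `ncol(states)-1`.
#' @return The matrix with class `ternary_series`.
#' @export
ternary_series <- function(states, region_labels = NULL, threshold = NA_real_,
                           transition_ok = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c(-1L, 0L, 1L)))
    stop("states must take values in {-1, 0, 1}")
  storage.mode(states) <- "integer"
  if (is.null(region_labels))
    region_labels <- rownames(states)
  if (is.null(region_labels))
    region_labels <- paste0("R", seq_len(nrow(states)))
  rownames(states) <- region_labels
  if (!is.null(transition_ok)) {
    stopifnot(is.logical(transition_ok),
              length(transition_ok) == ncol(states) - 1L)
    attr(states, "transition_ok") <- transition_ok
  }
  attr(states, "threshold") <- threshold
  class(states) <- c("ternary_series", class(states))
  states
}

#' @export
print.ternary_series <- function(x, ...) {
  cat(sprintf("<ternary_series> %d regions x %d time points (threshold %s)\n",
              nrow(x), ncol(x), format(attr(x, "threshold"))))
  invisible(x)
}

#' Z-score ROI time series row-wise
#'
#' Centres and scales each region's time course to mean 0 and unit
#' standard deviation.  The population convention (denominator `n`, not
#' `n - 1`) is used so that the transform is exactly idempotent.
#'
#' @param x Numeric matrix, rows = regions, columns = time points.
#' @return Matrix of the same shape with per-row mean 0 and population
#'   S.D. 1.
#' @export
#' @examples
#' zscore_rows(matrix(1:3, 1))  # -1.2247 0 1.2247
zscore_rows <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two time points")
  mu <- rowMeans(x)
  xc <- x - mu
  sd_pop <- sqrt(rowMeans(xc^2))
  if (any(sd_pop == 0)) {
    lab <- rownames(x)
    if (is.null(lab)) lab <- paste0("row ", seq_len(nrow(x)))
    stop("constant time series (zero variance) in: ",
         paste(lab[sd_pop == 0], collapse = ", "))
  }
  xc / sd_pop
}

#' Ternarize a z-scored signal by a symmetric threshold
#'
#' Entries strictly above `+threshold` become 1 (activation), strictly
#' below `-threshold` become -1 (deactivation), and everything in between
#' (inclusive of the boundaries) becomes 0 (null-activation).  The strict
#' inequality at the boundary is a fixed convention of the package.
#'
#' @param z Numeric matrix (normally the output of [zscore_rows()]) or
#'   vector.
#' @param threshold Positive threshold in S.D. units; the reference
#'   analysis sweeps 0.25, 0.50, 0.75 and 1.0.
#' @return A [ternary_series()] of the same shape.
#' @export
#' @examples
#' discretize(matrix(c(0.3, -1.2, 0.1), 1), 0.25)
discretize <- function(z, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  z <- as.matrix(z)
  s <- matrix(0L, nrow(z), ncol(z), dimnames = dimnames(z))
  s[z > threshold] <- 1L
  s[z < -threshold] <- -1L
  ternary_series(s, threshold = threshold)
}

#' Framewise-displacement scrubbing mask
#'
#' Flags scans whose framewise displacement exceeds `fd_limit`, dilates
#' each flag `pad_before` scans backwards and `pad_after` scans forwards
#' (the default 1 + 1 + 2 = 4 scans span 8 s at TR = 2 s), and marks the
#' subject for exclusion when more than `max_bad` scans are flagged.
#'
#' @param fd Nonnegative numeric vector, one framewise-displacement value
#'   per scan.
#' @param fd_limit Displacement limit in mm (default 0.2).
#' @param pad_before,pad_after Dilation of each flag, in scans (defaults
#'   1 and 2).
#' @param max_bad Subject-exclusion limit: excluded when `n_bad > max_bad`
#'   (default 30, i.e. more than 60 s of bad scans at TR = 2 s).
#' @return A list of class `scrub_mask` with elements `bad_scan` (logical
#'   per scan), `n_bad` and `subject_excluded`.
#' @export
#' @examples
#' scrub_fd(c(0.1, 0.1, 0.3, 0.1, 0.1, 0.1))$bad_scan
scrub_fd <- function(fd, fd_limit = 0.2, pad_before = 1L, pad_after = 2L,
                     max_bad = 30L) {
  if (length(fd) == 0L) stop("empty framewise-displacement vector")
  if (any(fd < 0)) stop("framewise displacement must be nonnegative")
  n <- length(fd)
  hit <- which(fd > fd_limit)
  bad <- rep(FALSE, n)
  for (i in hit) {
    lo <- max(1L, i - pad_before)
    hi <- min(n, i + pad_after)
    bad[lo:hi] <- TRUE
  }
  n_bad <- sum(bad)
  structure(list(bad_scan = bad, n_bad = n_bad,
                 subject_excluded = n_bad > max_bad),
            class = "scrub_mask")
}

#' @export
print.scrub_mask <- function(x, ...) {
  cat(sprintf("<scrub_mask> %d/%d bad scans; subject excluded: %s\n",
              x$n_bad, length(x$bad_scan), x$subject_excluded))
  invisible(x)
}

#' Splice scrubbed scans out of a series
#'
#' Drops the flagged time points and records, via the `transition_ok`
#' attribute, that transitions bridging a splice must not be counted as
#' consecutive-step events downstream.
#'
#' @param x A numeric matrix or [ternary_series()] (regions x time).
#' @param mask A [scrub_fd()] result (or logical vector of bad scans).
#' @return The spliced matrix; a `ternary_series` input keeps its class
#'   and gains/updates `transition_ok`.
#' @export
apply_scrub <- function(x, mask) {
  bad <- if (inherits(mask, "scrub_mask")) mask$bad_scan else as.logical(mask)
  stopifnot(length(bad) == ncol(x))
  keep <- which(!bad)
  if (length(keep) < 3L)
    stop("fewer than three scans survive scrubbing")
  # a kept transition is between two originally adjacent kept scans
  ok <- diff(keep) == 1L
  if (inherits(x, "ternary_series")) {
    thr <- attr(x, "threshold")
    ternary_series(unclass(x)[, keep, drop = FALSE], threshold = thr,
                   transition_ok = ok)
  } else {
    out <- x[, keep, drop = FALSE]
    attr(out, "transition_ok") <- ok
    out
  }
}

#' Read / write region x time series tables
#'
#' Plain tab-delimited text: one row per region, region label in the
#' first column, one column per time point.
#'
#' @param x Numeric matrix (rows = regions) or `ternary_series`.
#' @param path File path.
#' @return `read_series` returns a numeric matrix with region row names
#'   (use [ternary_series()] to re-assert state space if needed).
#' @export
write_series <- function(x, path) {
  df <- data.frame(region = rownames(x) %||% paste0("R", seq_len(nrow(x))),
                   unclass(x), check.names = FALSE)
  colnames(df) <- c("region", paste0("t", seq_len(ncol(x))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
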