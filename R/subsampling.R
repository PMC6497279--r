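# Frame-subsampling designs over an annotated frame sequence. Selection is
# positional over the usable frames of a transect: "interval 30" means
# every 30th usable frame from a random start.

#' Systematic frame selection
#'
#' Every `interval`-th index starting at `start`, i.e.
#' `{start, start + k, start + 2k, ...}` intersected with `1..N`. The
#' realized size is `floor((N - start) / k) + 1`.
#'
#' @param N Total number of frames (>= 1).
#' @param interval Sampling interval k (>= 1, <= N).
#' @param start First selected index, in `[1, interval]`.
#' @return Increasing integer vector of selected indices.
#' @export
systematic_select <- function(N, interval, start) {
  stopifnot(N >= 1, interval >= 1, interval <= N)
  if (start < 1 || start > interval) {
    stop("start must lie in [1, interval]", call. = FALSE)
  }
  seq.int(from = start, to = N, by = interval)
}

#' Random frame selection without replacement
#'
#' @param N Total number of frames.
#' @param n Sample size, `1 <= n <= N`.
#' @return Sorted integer vector of `n` distinct indices; reproducible
#'   under `set.seed()`.
#' @export
random_select <- function(N, n) {
  if (n > N) stop("sample size n exceeds N", call. = FALSE)
  stopifnot(n >= 1)
  sort(sample.int(N, n, replace = FALSE))
}

#' Logarithmically spaced sample sizes
#'
#' `k` sizes equally spaced on the log10 scale between `n_min` and
#' `n_max`, rounded to integers; endpoints are exact and duplicates after
#' rounding are removed with a warning.
#'
#' @param n_min,n_max Smallest and largest size, `n_min < n_max`.
#' @param k Number of sizes (>= 2).
#' @return Integer vector of at most `k` unique sizes.
#' @export
log_spaced_sizes <- function(n_min = 31, n_max = 1778, k = 36) {
  stopifnot(n_min >= 1, k >= 2)
  if (n_min >= n_max) stop("n_min must be < n_max", call. = FALSE)
  sizes <- round(10^seq(log10(n_min), log10(n_max), length.out = k))
  sizes[1] <- n_min
  sizes[k] <- n_max
  if (anyDuplicated(sizes)) {
    warning("duplicate sizes after rounding removed", call. = FALSE)
    sizes <- unique(sizes)
  }
  as.integer(sizes)
}

#' Default systematic intervals
#'
#' `k` unique integer intervals approximately log-spaced over
#' `[lo, hi]` (default 40 intervals over 5..300, matching the log-scale
#' analysis axis). Duplicates from rounding are bumped to the next unused
#' integer, deterministically.
#'
#' @param k Number of intervals.
#' @param lo,hi Interval range.
#' @return Increasing integer vector of length `k`.
#' @export
default_systematic_intervals <- function(k = 40, lo = 5, hi = 300) {
  stopifnot(k >= 1, lo >= 1, hi > lo, hi - lo + 1 >= k)
  raw <- round(10^seq(log10(lo), log10(hi), length.out = k))
  out <- integer(0)
  for (v in raw) {
    while (v %in% out) v <- v + 1L
    out <- c(out, v)
  }
  sort(as.integer(out))
}

#' Split a transect's frames into halves
#'
#' First half is frames `1..floor(N/2)` in sequence order, second half the
#' remainder; sizes differ by at most one.
#'
#' @param records `frame_records` for a single transect.
#' @return List of two `frame_records` tibbles, `first` and `second`.
#' @export
split_halves <- function(records) {
  stopifnot(nrow(records) >= 2)
  records <- records[order(records$frame_index), ]
  h <- floor(nrow(records) / 2)
  first <- records[seq_len(h), ]
  second <- records[(h + 1):nrow(records), ]
  class(first) <- class(second) <- class(records)
  list(first = first, second = second)
}

#' Define a subsampling design
#'
#' @param kind `"systematic"` (selection by interval, random start per
#'   replicate) or `"random"` (simple random sample of each size).
#' @param intervals Integer intervals (systematic designs).
#' @param sizes Integer sample sizes (random designs).
#' @param n_reps Replicates per interval/size (default 10).
#' @return A `subsample_design` list.
#' @export
subsample_design <- function(kind = c("systematic", "random"),
                             intervals = NULL, sizes = NULL, n_reps = 10) {
  kind <- match.arg(kind)
  stopifnot(n_reps >= 1)
  if (kind == "systematic") {
    if (is.null(intervals)) intervals <- default_systematic_intervals()
    stopifnot(all(intervals >= 1))
  } else {
    if (is.null(sizes)) sizes <- log_spaced_sizes()
    stopifnot(all(sizes >= 1))
  }
  structure(list(kind = kind, intervals = intervals, sizes = sizes,
                 n_reps = as.integer(n_reps)),
            class = "subsample_design")
}

#' Run a subsampling design over annotated frames
#'
#' For each interval (systematic; random start per replicate) or size
#' (random), draws `n_reps` subsamples of the usable frames, pools the
#' selected frames' counts at the requested rank, and computes H and N2.
#' Empty subsamples carry `NA` diversity.
#'
#' @param records `frame_records` (a single transect or a pooled sequence;
#'   selection is over usable frames in (transect, frame) order).
#' @param design A [subsample_design()].
#' @param taxonomy Taxonomy tibble (only needed above rank `"taxon"`).
#' @param rank Aggregation rank.
#' @param log_base Log base for H.
#' @return A `diversity_curve` tibble with columns kind, interval,
#'   size_nominal, n_frames, fraction_pct, rep, n_organisms, H, N2.
#'   For systematic rows `size_nominal` is the realized size and
#'   `interval` the design interval; for random rows `interval` is the
#'   equivalent interval `N / n` (the correspondence is reported both
#'   ways, not asserted).
#' @export
run_design <- function(records, design, taxonomy = NULL,
                       rank = c("taxon", "order", "class"),
                       log_base = exp(1)) {
  rank <- match.arg(rank)
  stopifnot(inherits(design, "subsample_design"))
  if (nrow(records) == 0) stop("no frames to sample", call. = FALSE)
  use <- records[records$usable %||% TRUE, , drop = FALSE]
  use <- use[order(use$transect_id, use$frame_index), ]
  N <- nrow(use)
  if (N == 0) stop("no usable frames to sample", call. = FALSE)
  cols <- taxon_columns(records)
  cnt <- as.matrix(use[cols])
  if (length(cols) == 0) cnt <- matrix(0, nrow = N, ncol = 0)

  row_for <- function(idx, kind, interval, size_nominal, rep) {
    v <- if (length(cols)) colSums(cnt[idx, , drop = FALSE]) else numeric(0)
    v <- aggregate_counts(setNames(as.numeric(v), cols), taxonomy, rank)
    d <- suppressWarnings(diversity_summary(v, log_base))
    tibble::tibble(kind = kind, interval = interval,
                   size_nominal = size_nominal, n_frames = length(idx),
                   fraction_pct = 100 * length(idx) / N, rep = rep,
                   n_organisms = d$n, H = d$H, N2 = d$N2)
  }

  rows <- list()
  if (design$kind == "systematic") {
    for (k in design$intervals) {
      if (k > N) stop("interval ", k, " exceeds usable frame count ", N,
                      call. = FALSE)
      for (r in seq_len(design$n_reps)) {
        start <- sample.int(k, 1)
        idx <- systematic_select(N, k, start)
        rows[[length(rows) + 1]] <- row_for(idx, "systematic", k, length(idx), r)
      }
    }
  } else {
    for (n in design$sizes) {
      if (n > N) stop("size ", n, " exceeds usable frame count ", N,
                      call. = FALSE)
      for (r in seq_len(design$n_reps)) {
        idx <- random_select(N, n)
        rows[[length(rows) + 1]] <- row_for(idx, "random", N / n, n, r)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("diversity_curve", class(out)))
  out
}
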