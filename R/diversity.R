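# Shannon H' = -sum p_i log p_i and Hill's N2 = 1 / sum p_i^2, computed
# from proportions of total organisms. Zero-count taxa are dropped before
# forming p (0 log 0 := 0); an empty assemblage yields NA with a warning
# rather than an error, so pipelines can carry the undefined marker.

#' Shannon diversity index
#'
#' `H = -sum(p * log(p))` with proportions `p` of total organisms per
#' taxon. Natural log by default (nats); `log_base` is configurable.
#'
#' @param v Named or unnamed non-negative abundance vector (counts, or
#'   estimated real-valued catches).
#' @param log_base Logarithm base, > 1. Default `exp(1)`.
#' @return Shannon H (>= 0), or `NA` with a warning when the vector sums
#'   to zero.
#' @export
shannon <- function(v, log_base = exp(1)) {
  stopifnot(log_base > 1)
  v <- v[v > 0]
  n <- sum(v)
  if (length(v) == 0 || n <= 0) {
    warning("diversity undefined for an empty assemblage", call. = FALSE)
    return(NA_real_)
  }
  p <- v / n
  -sum(p * log(p, base = log_base))
}

#' Hill's N2, the effective number of abundant species
#'
#' `N2 = 1 / sum(p^2)`; ranges from 1 (complete dominance) to S (uniform
#' assemblage of S taxa), and is robust to rare taxa.
#'
#' @inheritParams shannon
#' @return N2 in `[1, S]`, or `NA` with a warning for an empty assemblage.
#' @export
hills_n2 <- function(v) {
  v <- v[v > 0]
  n <- sum(v)
  if (length(v) == 0 || n <= 0) {
    warning("diversity undefined for an empty assemblage", call. = FALSE)
    return(NA_real_)
  }
  p <- v / n
  1 / sum(p^2)
}

#' Full diversity summary of one abundance vector
#'
#' @inheritParams shannon
#' @return One-row tibble with n (organisms), S (observed richness),
#'   H, N2 and log_base.
#' @export
diversity_summary <- function(v, log_base = exp(1)) {
  vv <- v[v > 0]
  tibble::tibble(
    n = sum(v),
    S = length(vv),
    H = suppressWarnings(shannon(v, log_base)),
    N2 = suppressWarnings(hills_n2(v)),
    log_base = log_base
  )
}

#' Per-group diversity table
#'
#' Computes H and N2 per transect (frame records) or per station (catch
#' records) at a chosen taxonomic rank, plus an `All` row. The `All` row
#' is computed from pooled counts by default; `all_mode = "mean"` instead
#' averages the per-group indices, for comparison with summaries whose
#' pooling rule is unstated.
#'
#' @param x `frame_records` or `catch_records`.
#' @param taxonomy Taxonomy tibble; default packaged survey taxonomy.
#' @param rank `"taxon"`, `"order"` or `"class"`.
#' @param log_base Logarithm base for H.
#' @param all_mode `"pooled"` (default) or `"mean"`.
#' @return Tibble with columns group, rank, n, S, H, N2, log_base; one row
#'   per group plus an `All` row. Groups with zero organisms carry `NA`.
#' @export
diversity_by_group <- function(x, taxonomy = NULL,
                               rank = c("taxon", "order", "class"),
                               log_base = exp(1),
                               all_mode = c("pooled", "mean")) {
  rank <- match.arg(rank)
  all_mode <- match.arg(all_mode)
  if (inherits(x, "frame_records")) {
    groups <- split(x, x$transect_id)
    groups <- lapply(groups, function(g) {
      class(g) <- unique(c("frame_records", class(g))); g
    })
  } else if (inherits(x, "catch_records")) {
    groups <- split(x, x$station_id)
    groups <- lapply(groups, function(g) {
      class(g) <- unique(c("catch_records", class(g))); g
    })
  } else {
    stop("x must be frame_records or catch_records", call. = FALSE)
  }
  if (length(groups) == 0) stop("no groups present", call. = FALSE)
  per <- dplyr::bind_rows(lapply(names(groups), function(nm) {
    v <- aggregate_counts(groups[[nm]], taxonomy, rank)
    dplyr::bind_cols(tibble::tibble(group = nm, rank = rank),
                     suppressWarnings(diversity_summary(v, log_base)))
  }))
  pooled_v <- aggregate_counts(x, taxonomy, rank)
  all_row <- dplyr::bind_cols(tibble::tibble(group = "All", rank = rank),
                              suppressWarnings(diversity_summary(pooled_v, log_base)))
  if (all_mode == "mean") {
    all_row$H <- mean(per$H, na.rm = TRUE)
    all_row$N2 <- mean(per$N2, na.rm = TRUE)
  }
  dplyr::bind_rows(per, all_row)
}
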