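# Community structure across transects or stations: centered/scaled count
# matrices, Euclidean distances, Ward minimum-variance clustering.
#
# Two Ward conventions circulate; this package uses the criterion on
# squared Euclidean distances, so each merge height equals the increase in
# total within-cluster sum of squares,
#   delta(A, B) = nA * nB / (nA + nB) * ||cA - cB||^2.
# That is hclust's "ward.D" on d^2 / 2 (the Lance-Williams update is
# linear, so halving the initial squared distances makes heights equal
# delta exactly).

#' Build a community count matrix
#'
#' Rows are groups (transects or stations), columns taxa (or orders or
#' classes). Frame records contribute per-transect pooled counts of usable
#' frames; catch records per-station counts. `effort_correct = TRUE`
#' divides each transect's counts by its number of usable frames
#' (counts per frame), for surveys with unequal annotation effort; the
#' default leaves raw counts.
#'
#' @param x `frame_records` or `catch_records`.
#' @param taxonomy Taxonomy tibble for ranks above `"taxon"`.
#' @param rank Aggregation rank.
#' @param effort_correct Divide transect counts by usable-frame count.
#' @return Numeric matrix, groups x taxa.
#' @export
community_matrix <- function(x, taxonomy = NULL,
                             rank = c("taxon", "order", "class"),
                             effort_correct = FALSE) {
  rank <- match.arg(rank)
  if (inherits(x, "frame_records")) {
    groups <- split(x, x$transect_id)
  } else if (inherits(x, "catch_records")) {
    groups <- split(x, x$station_id)
  } else stop("x must be frame_records or catch_records", call. = FALSE)
  vecs <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    class(g) <- class(x)
    v <- aggregate_counts(g, taxonomy, rank)
    if (effort_correct && inherits(x, "frame_records")) {
      v <- v / sum(g$usable)
    }
    v
  })
  taxa <- sort(unique(unlist(lapply(vecs, names))))
  m <- matrix(0, nrow = length(groups), ncol = length(taxa),
              dimnames = list(names(groups), taxa))
  for (i in seq_along(vecs)) m[i, names(vecs[[i]])] <- vecs[[i]]
  m
}

#' Center and scale a community matrix
#'
#' Each column is expressed as a residual from its mean and scaled to unit
#' sample standard deviation (n - 1 denominator). Zero-variance columns
#' carry no between-group information and are dropped with a warning.
#'
#' @param m Numeric matrix with >= 2 rows.
#' @return Standardized matrix.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("standardization needs >= 2 rows", call. = FALSE)
  sds <- apply(m, 2, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
    m <- m[, !zero, drop = FALSE]
  }
  scale(m)[, , drop = FALSE]
}

#' Euclidean distance matrix
#'
#' @param m Numeric matrix without missing values.
#' @return A `dist` object of pairwise Euclidean distances.
#' @export
euclidean_distances <- function(m) {
  if (anyNA(m)) stop("missing values in community matrix", call. = FALSE)
  stats::dist(m, method = "euclidean")
}

#' Ward minimum-variance clustering
#'
#' Agglomerative clustering that merges, at each step, the pair of
#' clusters whose fusion least increases the total within-cluster sum of
#' squares. Merge heights equal that increase and are non-decreasing.
#'
#' @param x A numeric matrix (rows clustered) or a Euclidean `dist`.
#' @return An `hclust` object with heights equal to the Ward merge costs.
#' @export
ward_cluster <- function(x) {
  d <- if (inherits(x, "dist")) x else euclidean_distances(x)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  if (attr(d, "Size") < 2) stop("need >= 2 items to cluster", call. = FALSE)
  stats::hclust(d^2 / 2, method = "ward.D")
}

#' Cut a dendrogram into k groups
#'
#' Undoes the k - 1 highest merges.
#'
#' @param tree An `hclust` object.
#' @param k Number of groups, `1 <= k <=` number of leaves.
#' @return Named integer vector of group labels.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]", call. = FALSE)
  stats::cutree(tree, k = k)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param tree An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Per-transect sediment composition
#'
#' Mean sediment percentages over frames carrying sediment data, per
#' transect, renormalized to proportions summing to one. Transects with no
#' sediment data carry `NA`.
#'
#' @param records `frame_records` with `sed_*` columns.
#' @return Tibble with transect_id and one proportion column per sediment
#'   class present.
#' @export
sediment_composition <- function(records) {
  sed <- sediment_columns(records)
  if (length(sed) == 0) stop("no sediment columns present", call. = FALSE)
  groups <- split(records, records$transect_id)
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    m <- as.matrix(g[sed])
    has <- rowSums(!is.na(m)) > 0 & rowSums(m, na.rm = TRUE) > 0
    if (!any(has)) {
      props <- setNames(rep(NA_real_, length(sed)), sed)
    } else {
      mm <- m[has, , drop = FALSE]
      mm[is.na(mm)] <- 0
      means <- colMeans(mm)
      props <- means / sum(means)
    }
    dplyr::bind_cols(tibble::tibble(transect_id = nm),
                     tibble::as_tibble(as.list(props)))
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- sub("^sed_", "", names(out))
  names(out)[1] <- "transect_id"
  out
}
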