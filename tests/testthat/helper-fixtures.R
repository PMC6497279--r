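# Small in-code fixtures shared across tests.

# frame records with known counts: frames 1..3, taxa sand_dollar / hermit
tiny_frames <- function() {
  frame_records(
    transect_id = "T1",
    frame_index = 1:3,
    counts = data.frame(sand_dollar = c(2L, 0L, 0L),
                        hermit = c(0L, 0L, 1L))
  )
}

# a two-taxon toy taxonomy
toy_taxonomy <- function() {
  tax <- tibble::tibble(
    common_name = c("sand_dollar", "hermit"),
    scientific_name = c("Echinarachnius parma", "Pagurus sp."),
    species = scientific_name,
    order = c("Clypeasteroida", "Decapoda"),
    class = c("Echinoidea", "Malacostraca")
  )
  class(tax) <- unique(c("taxonomy", class(tax)))
  tax
}

# named abundance vectors from the packaged survey count table
survey_vectors <- function() {
  sc <- survey_counts()
  list(
    beam_trawl = stats::setNames(sc$beam_trawl, sc$common_name),
    test_set = stats::setNames(sc$test_set, sc$common_name),
    transects = stats::setNames(sc$transects_1_7, sc$common_name)
  )
}

# frame records carrying every count of a vector in frame 1 of one transect
frames_from_vector <- function(v, transect = "T1") {
  frame_records(transect_id = transect, frame_index = 1L,
                counts = as.data.frame(as.list(v), check.names = FALSE))
}

# random abundance vector for property sweeps
random_abundance <- function(k, max_count = 50) {
  stats::setNames(sample.int(max_count, k, replace = TRUE), paste0("tx", seq_len(k)))
}

# independently coded tricube local-linear smoother (direct summation),
# mirroring lowess's neighbourhood definition: r = ceiling(f * n) nearest
# points by |x - x0|, tricube weights scaled by the window radius.
oracle_tricube_smooth <- function(x, y, f) {
  n <- length(x)
  r <- ceiling(f * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d, partial = r)[r]
    w <- numeric(n)
    in_win <- d <= h
    if (h > 0) {
      w[in_win] <- (1 - (d[in_win] / h)^3)^3
    } else {
      w[in_win] <- 1
    }
    xw <- x[w > 0]; yw <- y[w > 0]; ww <- w[w > 0]
    # weighted local linear fit evaluated at x[i]
    sw <- sum(ww); mx <- sum(ww * xw) / sw; my <- sum(ww * yw) / sw
    sxx <- sum(ww * (xw - mx)^2)
    if (sxx < 1e-12) return(my)
    b <- sum(ww * (xw - mx) * (yw - my)) / sxx
    my + b * (x[i] - mx)
  }, numeric(1))
}

# greedy Ward clustering by exhaustive evaluation of every greedy choice at
# each step, returning the minimum achievable sequence of merge costs
# (delta = nA*nB/(nA+nB) * ||cA - cB||^2)
oracle_ward_costs <- function(points) {
  ward_delta <- function(a, b) {
    ca <- colMeans(points[a, , drop = FALSE])
    cb <- colMeans(points[b, , drop = FALSE])
    (length(a) * length(b) / (length(a) + length(b))) * sum((ca - cb)^2)
  }
  recurse <- function(clusters, costs) {
    if (length(clusters) == 1) return(list(costs))
    pairs <- utils::combn(length(clusters), 2)
    deltas <- apply(pairs, 2, function(p) ward_delta(clusters[[p[1]]], clusters[[p[2]]]))
    best <- which(deltas == min(deltas))
    out <- list()
    for (b in best) {
      p <- pairs[, b]
      merged <- c(clusters[-p], list(c(clusters[[p[1]]], clusters[[p[2]]])))
      out <- c(out, recurse(merged, c(costs, deltas[b])))
    }
    out
  }
  seqs <- recurse(as.list(seq_len(nrow(points))), numeric(0))
  # greedy cost sequences can differ only under ties; return the first
  seqs[[1]]
}
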