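# Homogeneity diagnostic: hierarchical density-based clustering of a 1-D
# index. A healthy-cohort composite index should form one dense cloud;
# separated modes indicate a heterogeneous (suspect) index.
#
# Implementation note: this is a purpose-built 1-D analogue of the
# HDBSCAN idea — per-point core distances (distance to the k-th nearest
# neighbour) smooth the empirical density, adjacent points in sorted
# order are linked by their mutual reachability distance, and the sample
# is split wherever that distance jumps well above its typical level.
# Segments smaller than the minimum cluster size are labelled noise.

#' Density-based homogeneity check of a cohort index
#'
#' @param index_values numeric vector (>= 20 values)
#' @param min_cluster_size minimum cluster size (default 10)
#' @param split_factor a split is declared where the adjacent mutual
#'   reachability distance exceeds `split_factor` times its median
#'   (default 4)
#' @return list: `n_clusters`, `labels` (0 = noise, in input order),
#'   `homogeneous` flag (exactly one cluster holding >= 90% of non-noise
#'   points)
#' @export
homogeneity_check <- function(index_values, min_cluster_size = 10,
                              split_factor = 4) {
  x <- as.numeric(index_values)
  keep <- !is.na(x)
  xv <- x[keep]
  n <- length(xv)
  if (n < 20L) {
    stop("homogeneity_check needs at least 20 values", call. = FALSE)
  }
  ord <- order(xv)
  xs <- xv[ord]
  k <- min(min_cluster_size, n - 1L)
  # core distance: distance to the k-th nearest neighbour (1-D, via a
  # sliding window over the sorted values)
  core <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - k)
    hi <- min(n, i + k)
    d <- sort(abs(xs[lo:hi] - xs[i]))
    d[k + 1L]  # d[1] is the self-distance 0
  }, numeric(1))
  gaps <- diff(xs)
  mreach <- pmax(gaps, core[-n], core[-1L])
  med <- stats::median(mreach[mreach > 0])
  if (!length(med) || is.na(med) || med == 0) {
    # all values (numerically) identical: one perfectly dense cloud
    labels <- integer(length(x))
    labels[keep] <- 1L
    return(list(n_clusters = 1L, labels = labels, homogeneous = TRUE))
  }
  breaks <- which(mreach > split_factor * med)
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, n)
  lab_sorted <- integer(n)
  cl <- 0L
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    if (length(idx) >= min_cluster_size) {
      cl <- cl + 1L
      lab_sorted[idx] <- cl
    } # else noise (0)
  }
  labels_v <- integer(n)
  labels_v[ord] <- lab_sorted
  labels <- integer(length(x))
  labels[keep] <- labels_v
  labels[!keep] <- NA_integer_
  n_nonnoise <- sum(labels_v > 0)
  homog <- cl == 1L && n_nonnoise > 0 &&
    max(tabulate(labels_v[labels_v > 0])) >= 0.9 * n_nonnoise
  list(n_clusters = cl, labels = labels, homogeneous = homog)
}
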