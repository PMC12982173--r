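# From-scratch isolation forest for training-only outlier removal.
# An ensemble of random isolation trees; points isolated in few splits
# (short average path length) receive high anomaly scores.

# average unsuccessful-search path length in a BST of n nodes
iforest_c <- function(n) {
  if (n <= 1) return(0)
  h <- log(n - 1) + 0.5772156649015329
  2 * h - 2 * (n - 1) / n
}

build_itree <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1L || depth >= max_depth) {
    return(list(leaf = TRUE, size = n))
  }
  # pick a feature with spread; give up after a few attempts
  for (try in 1:10) {
    j <- sample.int(ncol(X), 1L)
    v <- X[idx, j]
    lo <- min(v); hi <- max(v)
    if (hi > lo) break
  }
  if (hi <= lo) return(list(leaf = TRUE, size = n))
  s <- stats::runif(1, lo, hi)
  left <- idx[v < s]
  right <- idx[v >= s]
  if (!length(left) || !length(right)) {
    return(list(leaf = TRUE, size = n))
  }
  list(leaf = FALSE, feature = j, split = s,
       left = build_itree(X, left, depth + 1L, max_depth),
       right = build_itree(X, right, depth + 1L, max_depth))
}

itree_path_length <- function(tree, x, depth = 0) {
  if (tree$leaf) return(depth + iforest_c(tree$size))
  if (x[tree$feature] < tree$split) {
    itree_path_length(tree$left, x, depth + 1)
  } else {
    itree_path_length(tree$right, x, depth + 1)
  }
}

#' Isolation-forest anomaly scores
#'
#' @param X numeric matrix (rows = observations); missing cells are
#'   median-filled per column for scoring purposes only
#' @param n_trees ensemble size (default 200)
#' @param sample_size subsample per tree (default min(256, n))
#' @param seed integer seed; scores are deterministic given it
#' @return numeric vector of scores in (0, 1); higher = more anomalous
#' @export
isolation_forest_scores <- function(X, n_trees = 200, sample_size = NULL,
                                    seed = 1L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- stats::median(X[, j], na.rm = TRUE)
  }
  n <- nrow(X)
  psi <- min(sample_size %||% 256L, n)
  max_depth <- ceiling(log2(max(psi, 2)))
  paths <- with_seed(seed, {
    acc <- numeric(n)
    for (b in seq_len(n_trees)) {
      idx <- sample.int(n, psi)
      tree <- build_itree(X, idx, 0L, max_depth)
      for (i in seq_len(n)) {
        acc[i] <- acc[i] + itree_path_length(tree, X[i, ])
      }
    }
    acc / n_trees
  })
  2^(-paths / iforest_c(psi))
}

#' Training-only outlier removal
#'
#' Scores rows with [isolation_forest_scores()] and flags the
#' `contamination` fraction with the highest anomaly scores
#' (`floor(n * contamination)` rows, matching the usual quantile
#' convention). Bookkeeping follows the total / detected / processed
#' format.
#'
#' @param train_table data.frame or matrix of numeric features (a
#'   `subject_id` column, if present, is ignored for scoring)
#' @param contamination fraction to flag, in [0, 0.5)
#' @param seed integer seed
#' @return list: `keep` (logical mask), `counts` (data.frame: total,
#'   detected, processed), `scores`
#' @export
remove_outliers <- function(train_table, contamination = 0.08, seed = 1L) {
  if (contamination >= 0.5) {
    stop("contamination must be < 0.5", call. = FALSE)
  }
  check_scalar(contamination, "contamination", lower = 0)
  df <- as.data.frame(train_table)
  df <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  X <- as.matrix(df[, num, drop = FALSE])
  n <- nrow(X)
  n_flag <- as.integer(floor(n * contamination + 1e-9))
  keep <- rep(TRUE, n)
  scores <- rep(NA_real_, n)
  if (n_flag > 0) {
    scores <- isolation_forest_scores(X, seed = seed)
    flagged <- order(scores, decreasing = TRUE)[seq_len(n_flag)]
    keep[flagged] <- FALSE
  }
  list(keep = keep,
       counts = data.frame(total = n, detected = n_flag,
                           processed = n - n_flag),
       scores = scores)
}
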