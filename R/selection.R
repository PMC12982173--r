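# Forward sequential feature selection with nested, leakage-safe
# preprocessing: train/test split, training-only outlier removal, median
# imputation, collinearity filtering, transformer search, forward
# selection by mean 5-fold cross-validated R-squared of OLS, and one
# final held-out evaluation.

#' Configuration for the selection pipeline
#'
#' @param max_features maximum forward-selection path length (default 40)
#' @param cv_folds number of CV folds (default 5)
#' @param collinearity_threshold pairwise |r| ceiling (default 0.7)
#' @param outlier_contamination isolation-forest contamination
#'   (default 0.08, i.e. 6-8 removals out of 90)
#' @param test_fraction held-out fraction (default 0.25)
#' @param feature_transformers,target_transformers grid axes
#' @param one_se use the one-standard-error rule to prefer smaller
#'   models (default TRUE); FALSE = plain argmax of mean CV R-squared
#' @param stratify stratify the split by target quartile (default TRUE)
#' @param seed integer seed
#' @return object of class `selection_config`
#' @export
selection_config <- function(max_features = 40, cv_folds = 5,
                             collinearity_threshold = 0.7,
                             outlier_contamination = 0.08,
                             test_fraction = 0.25,
                             feature_transformers = c("none", "quantile",
                                                      "yeo-johnson"),
                             target_transformers = c("none", "box-cox",
                                                     "yeo-johnson"),
                             one_se = TRUE, stratify = TRUE, seed = 1L) {
  check_scalar(max_features, "max_features", lower = 1)
  check_scalar(cv_folds, "cv_folds", lower = 2)
  check_scalar(collinearity_threshold, "collinearity_threshold",
               lower = 1e-9, upper = 1 - 1e-9)
  check_scalar(outlier_contamination, "outlier_contamination",
               lower = 0, upper = 0.5 - 1e-12)
  check_scalar(test_fraction, "test_fraction", lower = 0.01, upper = 0.9)
  structure(list(max_features = as.integer(max_features),
                 cv_folds = as.integer(cv_folds),
                 collinearity_threshold = collinearity_threshold,
                 outlier_contamination = outlier_contamination,
                 test_fraction = test_fraction,
                 feature_transformers = feature_transformers,
                 target_transformers = target_transformers,
                 one_se = one_se, stratify = stratify,
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Deterministic (optionally stratified) train/test split
#'
#' Stratifies by target quartile so both halves span the target range;
#' falls back to a simple random split (with a warning) when any stratum
#' is too small.
#'
#' @param y numeric target vector
#' @param test_fraction held-out fraction
#' @param seed integer seed
#' @param stratify logical
#' @return list with integer `train_idx` and `test_idx` (disjoint,
#'   covering all of `seq_along(y)`)
#' @export
split_train_test <- function(y, test_fraction = 0.25, seed = 1L,
                             stratify = TRUE) {
  n <- length(y)
  n_test <- round(n * test_fraction)
  test_idx <- with_seed(seed, {
    if (stratify) {
      qs <- stats::quantile(y, c(0.25, 0.5, 0.75), na.rm = TRUE)
      bins <- findInterval(y, unique(qs)) + 1L
      sizes <- table(bins)
      if (any(sizes < 2L)) {
        warning("stratum too small; falling back to simple random split",
                call. = FALSE)
        sort(sample.int(n, n_test))
      } else {
        raw <- sizes * test_fraction
        take <- floor(raw)
        rem <- n_test - sum(take)
        if (rem > 0) {
          extra <- order(raw - take, decreasing = TRUE)[seq_len(rem)]
          take[extra] <- take[extra] + 1L
        } else if (rem < 0) {
          shrink <- order(raw - take)[seq_len(-rem)]
          take[shrink] <- pmax(take[shrink] - 1L, 0L)
        }
        sort(unlist(lapply(seq_along(sizes), function(b) {
          pool <- which(bins == as.integer(names(sizes)[b]))
          sample(pool, min(take[b], length(pool)))
        }), use.names = FALSE))
      }
    } else {
      sort(sample.int(n, n_test))
    }
  })
  list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' Train-median imputation applied to both halves of a split
#'
#' Fill values are computed on the training table only; columns that are
#' entirely missing in training are dropped from both tables with a
#' warning.
#'
#' @param train_table,test_table data.frames/matrices sharing columns
#'   (`test_table` may be NULL)
#' @return list: `train`, `test` (completed numeric matrices), `fill`
#'   (named fill values), `dropped` (column names removed)
#' @export
impute_missing <- function(train_table, test_table = NULL) {
  tr <- as.matrix(as.data.frame(train_table))
  storage.mode(tr) <- "double"
  te <- if (!is.null(test_table)) {
    m <- as.matrix(as.data.frame(test_table))
    storage.mode(m) <- "double"
    m[, colnames(tr), drop = FALSE]
  }
  all_na <- apply(tr, 2L, function(v) all(is.na(v)))
  dropped <- colnames(tr)[all_na]
  if (length(dropped)) {
    warning("dropping all-missing training column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    tr <- tr[, !all_na, drop = FALSE]
    if (!is.null(te)) te <- te[, !all_na, drop = FALSE]
  }
  fill <- apply(tr, 2L, stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(tr))) {
    tr[is.na(tr[, j]), j] <- unname(fill[j])
    if (!is.null(te)) te[is.na(te[, j]), j] <- unname(fill[j])
  }
  list(train = tr, test = te, fill = fill, dropped = dropped)
}

#' Greedy collinearity filter
#'
#' Repeatedly finds the feature pair with the highest pairwise |Pearson
#' r| above the threshold and drops the member with the weaker |Pearson
#' correlation to the training target| (ties broken by column order).
#' The retained set is guaranteed to have max pairwise |r| <= threshold.
#'
#' @param train_table completed numeric training matrix
#' @param target numeric training target
#' @param threshold pairwise |r| ceiling (default 0.7)
#' @return list: `retained` (column names), `dropped` (data.frame:
#'   dropped, kept, r)
#' @export
drop_collinear <- function(train_table, target, threshold = 0.7) {
  X <- as.matrix(train_table)
  keep <- rep(TRUE, ncol(X))
  names(keep) <- colnames(X)
  sds <- apply(X, 2L, stats::sd)
  C <- suppressWarnings(abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  ty <- suppressWarnings(abs(stats::cor(X, target)))
  ty[!is.finite(ty)] <- 0
  log <- list()
  repeat {
    act <- which(keep)
    sub <- C[act, act, drop = FALSE]
    m <- max(sub)
    if (m <= threshold) break
    hit <- which(sub == m, arr.ind = TRUE)[1L, ]
    i <- act[min(hit)]; j <- act[max(hit)]
    drop_j <- if (ty[i] > ty[j]) j else if (ty[j] > ty[i]) i else j
    keep_i <- if (drop_j == j) i else j
    keep[drop_j] <- FALSE
    log[[length(log) + 1L]] <-
      data.frame(dropped = colnames(X)[drop_j],
                 kept = colnames(X)[keep_i], r = m)
  }
  # constant columns carry no information and break later correlations
  keep[sds == 0] <- FALSE
  list(retained = colnames(X)[keep],
       dropped = if (length(log)) do.call(rbind, log) else
         data.frame(dropped = character(0), kept = character(0),
                    r = numeric(0)))
}

# OLS helpers -----------------------------------------------------------

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  cf
}

ols_predict <- function(coef, X) {
  drop(cbind(1, X) %*% coef)
}

r2_score <- function(y_true, y_pred) {
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / sst
}

# mean CV R2 (original target scale) of OLS on a fixed feature set
cv_r2 <- function(X, y, folds, y_orig, inverse) {
  ks <- sort(unique(folds))
  fold_r2 <- vapply(ks, function(k) {
    tr <- folds != k
    cf <- ols_fit(X[tr, , drop = FALSE], y[tr])
    pred <- inverse(ols_predict(cf, X[!tr, , drop = FALSE]))
    r2_score(y_orig[!tr], pred)
  }, numeric(1))
  fold_r2
}

#' Forward sequential feature selection by cross-validated R-squared
#'
#' Starts from the empty set; at each step evaluates every remaining
#' candidate by the mean k-fold CV R-squared of OLS on (current set +
#' candidate) and adds the argmax (ties resolved to the lowest column
#' index), up to `max_features`. The reported choice of model size
#' maximises mean CV R-squared; with `one_se = TRUE` the smallest size
#' within one standard error of that maximum is preferred.
#'
#' When the target was transformed, pass the original-scale target as
#' `y_orig` and the inverse transform as `inverse`: fold predictions are
#' back-transformed before scoring, so cells of a transformer grid are
#' comparable.
#'
#' @param X completed numeric training feature matrix
#' @param y (possibly transformed) training target
#' @param max_features path length cap
#' @param cv_folds number of folds
#' @param seed integer seed for the fold assignment
#' @param one_se apply the one-standard-error rule
#' @param y_orig original-scale target (default `y`)
#' @param inverse inverse target transform (default identity)
#' @return list of class `forward_path`: `path` (data.frame: step,
#'   feature, mean_cv_r2, se_cv_r2), `chosen_k`, `selected` (feature
#'   names), `cv_r2` (mean CV R-squared at the chosen size), `folds`
#' @export
forward_select <- function(X, y, max_features = 40, cv_folds = 5,
                           seed = 1L, one_se = TRUE, y_orig = NULL,
                           inverse = identity) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 1L) stop("forward_select needs at least one candidate",
                   call. = FALSE)
  if (is.null(y_orig)) y_orig <- y
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep(seq_len(cv_folds),
                                      length.out = n)))
  max_k <- min(max_features, p)
  sel <- integer(0)
  path <- vector("list", max_k)
  for (step in seq_len(max_k)) {
    cand <- setdiff(seq_len(p), sel)
    best_j <- NA_integer_
    best_mean <- -Inf
    best_folds <- NULL
    for (j in cand) {
      fr <- cv_r2(X[, c(sel, j), drop = FALSE], y, folds, y_orig, inverse)
      m <- mean(fr)
      if (is.finite(m) && m > best_mean) {
        best_mean <- m
        best_j <- j
        best_folds <- fr
      }
    }
    if (is.na(best_j)) break
    sel <- c(sel, best_j)
    path[[step]] <- data.frame(
      step = step, feature = colnames(X)[best_j],
      mean_cv_r2 = best_mean,
      se_cv_r2 = stats::sd(best_folds) / sqrt(length(best_folds)))
  }
  path <- do.call(rbind, path[!vapply(path, is.null, logical(1))])
  k_star <- which.max(path$mean_cv_r2)
  chosen_k <- if (one_se) {
    thr <- path$mean_cv_r2[k_star] - path$se_cv_r2[k_star]
    min(which(path$mean_cv_r2 >= thr))
  } else {
    k_star
  }
  structure(list(path = path, chosen_k = chosen_k,
                 selected = path$feature[seq_len(chosen_k)],
                 cv_r2 = path$mean_cv_r2[chosen_k], folds = folds),
            class = "forward_path")
}

#' Grid search over feature/target transformers
#'
#' Runs [forward_select()] for every cell of the transformer grid
#' (feature: none / quantile / yeo-johnson; target: none / box-cox /
#' yeo-johnson), skipping Box-Cox cells with a message when the training
#' target has non-positive values, and returns the cell with the highest
#' mean CV R-squared at its chosen size plus the full grid table.
#'
#' @param X completed, collinearity-filtered training feature matrix
#' @param y original-scale training target
#' @param config a [selection_config()]
#' @return list: `best` (feature_transformer, target_transformer,
#'   methods, `forward` path), `grid` (data.frame: one row per evaluated
#'   or skipped cell), `skipped`
#' @export
search_transformers <- function(X, y, config = selection_config()) {
  grid_rows <- list()
  skipped <- character(0)
  best <- NULL
  for (ftm in config$feature_transformers) {
    ft <- fit_feature_transformer(X, ftm)
    Xt <- apply_feature_transformer(ft, X)
    for (ttm in config$target_transformers) {
      cell <- paste(ftm, ttm, sep = " / ")
      if (ttm == "box-cox" && any(y <= 0, na.rm = TRUE)) {
        message("skipping transformer cell '", cell,
                "': target has non-positive values")
        skipped <- c(skipped, cell)
        grid_rows[[length(grid_rows) + 1L]] <-
          data.frame(feature_transformer = ftm, target_transformer = ttm,
                     n_selected = NA_integer_, cv_r2 = NA_real_,
                     skipped = TRUE)
        next
      }
      tt <- fit_target_transformer(y, ttm)
      fw <- forward_select(Xt, tt$transform(y),
                           max_features = config$max_features,
                           cv_folds = config$cv_folds,
                           seed = substream_seed(config$seed, "cv-folds"),
                           one_se = config$one_se,
                           y_orig = y, inverse = tt$inverse)
      grid_rows[[length(grid_rows) + 1L]] <-
        data.frame(feature_transformer = ftm, target_transformer = ttm,
                   n_selected = fw$chosen_k, cv_r2 = fw$cv_r2,
                   skipped = FALSE)
      if (is.null(best) || fw$cv_r2 > best$cv_r2) {
        best <- list(feature_transformer = ft, target_transformer = tt,
                     feature_method = ftm, target_method = ttm,
                     forward = fw, cv_r2 = fw$cv_r2)
      }
    }
  }
  if (is.null(best)) {
    stop("empty transformer grid after skips", call. = FALSE)
  }
  list(best = best, grid = do.call(rbind, grid_rows), skipped = skipped)
}

#' Evaluate a fitted selection pipeline on held-out data
#'
#' Applies the train-fitted imputation, feature transform and selected
#' model to the test features, back-transforms predictions to the
#' original target scale, and returns `1 - SSres/SStot` (which may be
#' negative).
#'
#' @param result a `selection_result` from [select_features()]
#' @param test_features data.frame/matrix of raw test features
#' @param test_target numeric test target
#' @return held-out R-squared
#' @export
evaluate_heldout <- function(result, test_features, test_target) {
  if (length(test_target) < 3L) {
    stop("need at least 3 test subjects", call. = FALSE)
  }
  preds <- predict_selection(result, test_features)
  r2_score(as.numeric(test_target), preds)
}

#' @rdname evaluate_heldout
#' @export
predict_selection <- function(result, test_features) {
  df <- as.data.frame(test_features)
  df <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  te <- as.matrix(df)
  storage.mode(te) <- "double"
  te <- te[, names(result$fill), drop = FALSE]
  for (j in seq_len(ncol(te))) {
    te[is.na(te[, j]), j] <- result$fill[j]
  }
  te <- te[, result$retained, drop = FALSE]
  tet <- apply_feature_transformer(result$feature_transformer, te)
  z <- ols_predict(result$coefficients,
                   tet[, result$selected, drop = FALSE])
  result$target_transformer$inverse(z)
}

#' Run the full selection pipeline for one target
#'
#' Order of operations (all fitting on training data only): train/test
#' split (stratified by target quartile), isolation-forest outlier
#' removal on the training rows, train-median imputation, collinearity
#' filtering at the configured threshold, transformer grid search with
#' forward selection nested inside cross-validation, final OLS refit on
#' the full training set, and a single held-out evaluation.
#'
#' @param features data.frame: `subject_id` + numeric feature columns
#' @param targets data.frame: `subject_id` + target columns
#' @param target name of the target column to model
#' @param config a [selection_config()]
#' @param split optional precomputed split (list with `train_idx`,
#'   `test_idx`); when NULL it is drawn from the config seed
#' @return object of class `selection_result`: selected path, chosen k,
#'   train CV R-squared, held-out test R-squared, final coefficients,
#'   transformer choice, outlier bookkeeping (total/detected/processed),
#'   the transformer grid, dropped columns and the split
#' @export
select_features <- function(features, targets, target,
                            config = selection_config(), split = NULL) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  if (!target %in% names(targets)) {
    stop("target column '", target, "' not found", call. = FALSE)
  }
  common <- intersect(features$subject_id, targets$subject_id)
  f <- features[match(common, features$subject_id), , drop = FALSE]
  y <- as.numeric(targets[[target]][match(common, targets$subject_id)])
  fcols <- setdiff(names(f), "subject_id")
  X <- as.matrix(f[, fcols, drop = FALSE])
  storage.mode(X) <- "double"

  if (is.null(split)) {
    split <- split_train_test(y, config$test_fraction,
                              seed = substream_seed(config$seed, "split"),
                              stratify = config$stratify)
  }
  tr_i <- split$train_idx
  te_i <- split$test_idx

  out <- remove_outliers(X[tr_i, , drop = FALSE],
                         contamination = config$outlier_contamination,
                         seed = substream_seed(config$seed, "iforest"))
  tr_keep <- tr_i[out$keep]

  imp <- impute_missing(X[tr_keep, , drop = FALSE],
                        X[te_i, , drop = FALSE])
  coll <- drop_collinear(imp$train, y[tr_keep],
                         threshold = config$collinearity_threshold)
  Xtr <- imp$train[, coll$retained, drop = FALSE]

  search <- search_transformers(Xtr, y[tr_keep], config)
  best <- search$best
  Xtr_t <- apply_feature_transformer(best$feature_transformer, Xtr)
  yt <- best$target_transformer$transform(y[tr_keep])
  cf <- ols_fit(Xtr_t[, best$forward$selected, drop = FALSE], yt)

  result <- structure(list(
    target = target,
    path = best$forward$path,
    chosen_k = best$forward$chosen_k,
    selected = best$forward$selected,
    train_cv_r2 = best$forward$cv_r2,
    coefficients = cf,
    feature_transformer = best$feature_transformer,
    target_transformer = best$target_transformer,
    transformer_choice = c(feature = best$feature_method,
                           target = best$target_method),
    grid = search$grid,
    skipped_cells = search$skipped,
    outlier_counts = out$counts,
    fill = imp$fill,
    retained = coll$retained,
    dropped_collinear = coll$dropped,
    split = split,
    config = config), class = "selection_result")
  result$test_r2 <- evaluate_heldout(result, f[te_i, , drop = FALSE],
                                     y[te_i])
  result
}
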