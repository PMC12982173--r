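# Split, outlier removal, imputation, collinearity filter, forward
# selection, transformer search and held-out evaluation.

test_that("split_train_test partitions deterministically with stratification", {
  set.seed(1)
  y <- stats::rnorm(90)
  sp <- split_train_test(y, 0.25, seed = 5)
  expect_true(length(sp$test_idx) %in% c(22L, 23L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:90)
  expect_identical(split_train_test(y, 0.25, seed = 5), sp)
  expect_warning(split_train_test(stats::rnorm(6), 0.25, seed = 1),
                 "stratum")
})

test_that("remove_outliers isolates a planted gross outlier", {
  found <- vapply(1:20, function(s) {
    set.seed(s)
    X <- rbind(matrix(stats::rnorm(89 * 15), 89), rep(10, 15))
    ro <- remove_outliers(X, contamination = 1 / 90, seed = s)
    identical(which(!ro$keep), 90L)
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("remove_outliers bookkeeping and guards", {
  X <- matrix(stats::rnorm(50 * 5), 50)
  ro0 <- remove_outliers(X, contamination = 0, seed = 1)
  expect_true(all(ro0$keep))
  expect_identical(ro0$counts$detected, 0L)
  ro <- remove_outliers(X, contamination = 0.1, seed = 1)
  expect_identical(ro$counts$processed, ro$counts$total - ro$counts$detected)
  expect_identical(ro$counts$detected, 5L)
  expect_error(remove_outliers(X, contamination = 0.6), "0.5")
  # deterministic given seed
  expect_identical(remove_outliers(X, 0.1, seed = 3)$keep,
                   remove_outliers(X, 0.1, seed = 3)$keep)
})

test_that("impute_missing uses train-only medians", {
  tr <- data.frame(a = c(1, 3, NA), b = c(2, 2, 2))
  te <- data.frame(a = c(NA, 10), b = c(NA, 1))
  imp <- impute_missing(tr, te)
  expect_equal(unname(imp$train[3, "a"]), 2)
  expect_equal(unname(imp$test[1, "a"]), 2)
  expect_equal(unname(imp$test[1, "b"]), 2)
  # no missing cells: unchanged
  imp2 <- impute_missing(data.frame(a = 1:3), data.frame(a = 4:5))
  expect_equal(imp2$train[, "a"], 1:3, ignore_attr = TRUE)
  # mutating the test table cannot change fill values
  te_mut <- te; te_mut$a <- c(1e6, 1e6)
  expect_identical(impute_missing(tr, te_mut)$fill, imp$fill)
  # all-missing train column dropped from both
  expect_warning(
    imp3 <- impute_missing(data.frame(a = c(NA_real_, NA_real_),
                                      b = c(1, 2)),
                           data.frame(a = c(1, 2), b = c(3, 4))),
    "all-missing")
  expect_identical(colnames(imp3$train), "b")
  expect_identical(colnames(imp3$test), "b")
})

test_that("drop_collinear keeps the informative member and meets its bound", {
  # duplicated column: exactly one copy retained
  set.seed(2)
  x <- stats::rnorm(60)
  X <- cbind(a = x, b = x, c = stats::rnorm(60))
  dc <- drop_collinear(X, target = x + stats::rnorm(60, 0, 0.1))
  expect_length(intersect(c("a", "b"), dc$retained), 1L)

  # planted rho = 0.9 pair, only member i informative
  kept_inf <- vapply(1:20, function(s) {
    ch <- generate_cohort(cohort_spec(
      n_subjects = 90, n_features = 20,
      informative = list(beck = list(features = 1L, betas = 1)),
      r2_true = c(pcl5 = 0.3, phq9 = 0.3, beck = 0.5, conclusion = 0.3),
      collinear_pairs = data.frame(i = 1, j = 10, rho = 0.9),
      outlier_fraction = 0, missing_fraction = 0, seed = s))
    X <- as.matrix(ch$features[, -1])
    dc <- drop_collinear(X, ch$targets$beck)
    "F001" %in% dc$retained && !("F010" %in% dc$retained)
  }, logical(1))
  expect_gte(mean(kept_inf), 0.5)

  # post-condition on arbitrary input
  set.seed(9)
  Z <- matrix(stats::rnorm(60 * 12), 60)
  Z[, 2] <- Z[, 1] * 0.95 + stats::rnorm(60, 0, 0.1)
  Z[, 5] <- -Z[, 4]
  colnames(Z) <- letters[1:12]
  dc2 <- drop_collinear(Z, stats::rnorm(60))
  C <- abs(stats::cor(Z[, dc2$retained]))
  diag(C) <- 0
  expect_lte(max(C), 0.7)
})

test_that("forward_select finds a dominant predictor first (brute-force oracle)", {
  set.seed(3)
  n <- 60
  X <- matrix(stats::rnorm(n * 10), n, dimnames = list(NULL, paste0("x", 1:10)))
  y <- 2 * X[, 1] + stats::rnorm(n, 0, 0.01)
  fw <- forward_select(X, y, max_features = 3, cv_folds = 5, seed = 1)
  expect_identical(fw$path$feature[1], "x1")
  # exhaustive size-1 oracle: best single feature by in-sample R2
  r2s <- apply(X, 2, function(v) summary(stats::lm(y ~ v))$r.squared)
  expect_identical(names(which.max(r2s)), "x1")
  # nested path and non-decreasing in-sample fit
  ssr <- vapply(seq_len(nrow(fw$path)), function(k) {
    sel <- fw$path$feature[1:k]
    sum(stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)$residuals^2)
  }, numeric(1))
  expect_true(all(diff(ssr) <= 1e-9))
  expect_error(forward_select(X[, 0, drop = FALSE], y), "candidate")
})

test_that("forward_select is deterministic and its path is nested", {
  ch <- clean_planted_cohort(4)
  X <- as.matrix(ch$features[, 2:31])
  y <- ch$targets$beck
  f1 <- forward_select(X, y, max_features = 8, cv_folds = 5, seed = 2)
  f2 <- forward_select(X, y, max_features = 8, cv_folds = 5, seed = 2)
  expect_identical(f1$path, f2$path)
  expect_identical(f1$selected, f1$path$feature[seq_len(f1$chosen_k)])
  # one-SE rule never chooses more features than the argmax
  f3 <- forward_select(X, y, max_features = 8, cv_folds = 5, seed = 2,
                       one_se = FALSE)
  expect_lte(f1$chosen_k, f3$chosen_k)
  expect_identical(f3$chosen_k, which.max(f3$path$mean_cv_r2))
})

test_that("transformers behave: lambda-1 identity, box-cox guard, grid shape", {
  set.seed(6)
  x <- stats::rnorm(100, 5, 2)
  # Yeo-Johnson with lambda = 1 is the identity
  expect_equal(cardioscreen:::yj_transform(x, 1), x, tolerance = 1e-12)
  expect_equal(cardioscreen:::yj_inverse(cardioscreen:::yj_transform(x, 0.3),
                                         0.3), x, tolerance = 1e-8)
  # box-cox needs positive targets
  expect_error(fit_target_transformer(c(-1, 1, 2), "box-cox"), "positive")

  ch <- clean_planted_cohort(6)
  X <- as.matrix(ch$features[, 2:21])
  y <- ch$targets$beck  # contains non-positive values
  cfg <- selection_config(max_features = 4,
                          feature_transformers = "none",
                          target_transformers = c("none", "box-cox"),
                          seed = 1)
  msgs <- capture_messages(st <- search_transformers(X, y, cfg))
  expect_match(paste(msgs, collapse = " "), "non-positive")
  expect_identical(nrow(st$grid), 2L)
  expect_true(st$grid$skipped[st$grid$target_transformer == "box-cox"])
  expect_identical(st$best$target_method, "none")
})

test_that("quantile transform maps training data to a standard normal shape", {
  set.seed(7)
  X <- matrix(stats::rexp(500), ncol = 1)
  ft <- fit_feature_transformer(X, "quantile")
  z <- apply_feature_transformer(ft, X)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::sd(z) - 1), 0.1)
  # monotone
  expect_identical(order(z), order(X))
})

test_that("select_features runs end-to-end, deterministically, without leakage", {
  ch <- clean_planted_cohort(42)
  cfg <- fast_config(seed = 9)
  sp <- split_train_test(ch$targets$beck, 0.25, seed = 99)
  r1 <- select_features(ch$features, ch$targets, "beck", cfg, split = sp)
  # evaluating on the training rows reproduces the in-sample R2 of the
  # final model (self-consistency of the prediction path)
  tr_feats <- ch$features[sp$train_idx, ]
  tr_y <- ch$targets$beck[sp$train_idx]
  preds <- predict_selection(r1, tr_feats)
  manual <- 1 - sum((tr_y - preds)^2) / sum((tr_y - mean(tr_y))^2)
  expect_equal(evaluate_heldout(r1, tr_feats, tr_y), manual,
               tolerance = 1e-12)
  expect_error(evaluate_heldout(r1, tr_feats[1:2, ], tr_y[1:2]), "3 test")

  # leakage guard: corrupting test-side targets changes nothing train-side
  t2 <- ch$targets
  set.seed(1)
  t2$beck[sp$test_idx] <- stats::rnorm(length(sp$test_idx))
  r2 <- select_features(ch$features, t2, "beck", cfg, split = sp)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$train_cv_r2, r2$train_cv_r2)
  expect_identical(r1$transformer_choice, r2$transformer_choice)
  expect_identical(r1$coefficients, r2$coefficients)
  expect_false(isTRUE(all.equal(r1$test_r2, r2$test_r2)))

  # bit-identical rerun
  r3 <- select_features(ch$features, ch$targets, "beck", cfg, split = sp)
  expect_identical(r1$path, r3$path)
  expect_identical(r1$test_r2, r3$test_r2)

  # bookkeeping identity
  expect_identical(r1$outlier_counts$processed,
                   r1$outlier_counts$total - r1$outlier_counts$detected)
  expect_error(select_features(ch$features, ch$targets, "nope", cfg),
               "not found")
})

test_that("null cohort yields no optimistic held-out score", {
  r2s <- vapply(1:8, function(s) {
    ch <- null_cohort(s)
    cfg <- fast_config(seed = s)
    select_features(ch$features, ch$targets, "beck", cfg)$test_r2
  }, numeric(1))
  expect_lte(stats::median(r2s), 0.05)
})
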