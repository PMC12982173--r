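# Correlation screening of every feature against each psychological
# target, with tiered significance summaries. P-values are raw (no
# multiple-testing correction), matching the screening convention of
# small-cohort exploratory studies; a Benjamini-Hochberg option exists
# but is off by default.

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment r on pairwise-complete observations; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (missing values dropped pairwise;
#'   >= 3 complete pairs, both non-constant)
#' @param feature,target optional labels carried into the result
#' @return data.frame row of class `correlation_result`: feature, target,
#'   method, coefficient, p_value, n_used
#' @export
pearson_with_p <- function(x, y, feature = "x", target = "y") {
  ok <- stats::complete.cases(x, y)
  xv <- as.numeric(x[ok]); yv <- as.numeric(y[ok])
  n <- length(xv)
  if (n < 3L) {
    stop("need >= 3 pairwise-complete observations", call. = FALSE)
  }
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- stats::cor(xv, yv)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(data.frame(feature = feature, target = target,
                       method = "pearson", coefficient = r,
                       p_value = p, n_used = n),
            class = c("correlation_result", "data.frame"))
}

#' Spearman correlation with a two-sided p-value
#'
#' Pearson on mid-ranks (ties averaged); p-value via the same
#' t-approximation as [pearson_with_p()].
#'
#' @inheritParams pearson_with_p
#' @return as [pearson_with_p()], method "spearman"
#' @export
spearman_with_p <- function(x, y, feature = "x", target = "y") {
  ok <- stats::complete.cases(x, y)
  res <- pearson_with_p(rank(as.numeric(x[ok])), rank(as.numeric(y[ok])),
                        feature = feature, target = target)
  res$method <- "spearman"
  res
}

#' Screen every feature against every target with tiered summaries
#'
#' For each target and method, correlates each feature column (pairwise-
#' complete deletion per pair), sorts by p-value, and counts features per
#' significance tier. Tiers are exclusive bins by default (a p = 0.005
#' feature counts under "p < 0.01" only), which is how published tier
#' summaries add up against the per-feature tables.
#'
#' @param features data.frame with `subject_id` + numeric feature columns
#' @param targets data.frame with `subject_id` + numeric target columns
#' @param tiers increasing p thresholds (default 0.001, 0.01, 0.05, 0.1)
#' @param methods correlation methods to run
#' @param exclusive logical: count tiers as exclusive bins (default TRUE)
#' @param bh_adjust apply Benjamini-Hochberg within each target/method
#'   before binning (default FALSE, matching raw-p reporting)
#' @return list: `results` (all correlation rows, sorted by p within
#'   target/method), `tier_counts` (data.frame method x target x tier),
#'   `strict_tables` (per target: rows with p below the second tier,
#'   e.g. p < 0.01) and `extended_tables` (p below the third tier,
#'   e.g. p < 0.05) — both labelled explicitly
#' @export
correlation_screen <- function(features, targets,
                               tiers = c(0.001, 0.01, 0.05, 0.1),
                               methods = c("pearson", "spearman"),
                               exclusive = TRUE, bh_adjust = FALSE) {
  stopifnot(is.data.frame(features), is.data.frame(targets),
            "subject_id" %in% names(features),
            "subject_id" %in% names(targets))
  common <- intersect(features$subject_id, targets$subject_id)
  if (!length(common)) {
    stop("no overlapping subjects between features and targets",
         call. = FALSE)
  }
  f <- features[match(common, features$subject_id), , drop = FALSE]
  tg <- targets[match(common, targets$subject_id), , drop = FALSE]
  fcols <- setdiff(names(f), "subject_id")
  fcols <- fcols[vapply(f[fcols], is.numeric, logical(1))]
  tcols <- setdiff(names(tg), "subject_id")
  tiers <- sort(tiers)

  rows <- list()
  for (m in methods) {
    fun <- if (m == "pearson") pearson_with_p else spearman_with_p
    for (tv in tcols) {
      for (fc in fcols) {
        r <- tryCatch(fun(f[[fc]], tg[[tv]], feature = fc, target = tv),
                      error = function(e) NULL)
        if (!is.null(r)) rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$method, res$target, res$p_value), ]
  rownames(res) <- NULL

  p_for_bins <- function(d) {
    if (bh_adjust) stats::p.adjust(d$p_value, "BH") else d$p_value
  }
  counts <- list()
  for (m in methods) {
    for (tv in tcols) {
      d <- res[res$method == m & res$target == tv, ]
      p <- p_for_bins(d)
      for (i in seq_along(tiers)) {
        n_in <- if (exclusive) {
          lo <- if (i == 1L) 0 else tiers[i - 1L]
          sum(p < tiers[i] & p >= lo)
        } else {
          sum(p < tiers[i])
        }
        counts[[length(counts) + 1L]] <-
          data.frame(method = m, target = tv, tier = tiers[i],
                     count = n_in)
      }
    }
  }
  tier_counts <- do.call(rbind, counts)

  tab_at <- function(thr) {
    lapply(stats::setNames(tcols, tcols), function(tv) {
      d <- res[res$target == tv & res$p_value < thr, ]
      d <- d[order(d$p_value), ]
      d$rank <- seq_len(nrow(d))
      rownames(d) <- NULL
      d[, c("rank", "feature", "method", "coefficient", "p_value",
            "n_used")]
    })
  }
  list(results = res, tier_counts = tier_counts,
       strict_label = sprintf("p < %g", tiers[2L]),
       extended_label = sprintf("p < %g", tiers[3L]),
       strict_tables = tab_at(tiers[2L]),
       extended_tables = tab_at(tiers[3L]))
}
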