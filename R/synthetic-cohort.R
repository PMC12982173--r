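# Synthetic cohort generator: a subjects x features table with a planted
# linear signal to each of the four psychological targets, planted
# collinear pairs, gross outlier rows and missing cells — so screening and
# selection can be validated against known ground truth.

TARGET_NAMES <- c("pcl5", "phq9", "beck", "conclusion")

#' Cohort specification for the synthetic feature/target tables
#'
#' The default world emulates a ~90-subject cohort measured on ~120
#' ECG/HRV parameters, with a planted linear signal per psychological
#' target. Population R-squared per target defaults to values in the
#' range of published small-cohort regressions of this kind (strongest
#' for the anxiety target); the fourth target is an ordinal 1-4
#' psychologist's conclusion obtained by quartile discretisation.
#'
#' @param n_subjects number of subjects (default 90)
#' @param n_features number of features (default 120)
#' @param informative named list over targets (`pcl5`, `phq9`, `beck`,
#'   `conclusion`); each element a list with integer `features` (column
#'   indices) and numeric `betas`. NULL plants the default signal.
#' @param noise_sd named numeric vector of target noise SDs. NULL derives
#'   noise from `r2_true` given the planted betas.
#' @param r2_true named numeric population R-squared per target, used only
#'   when `noise_sd` is NULL
#' @param collinear_pairs data.frame with columns `i`, `j`, `rho`; feature
#'   j is rebuilt as `rho * f_i + sqrt(1 - rho^2) * z`
#' @param outlier_fraction fraction of rows receiving gross shifts
#'   (>= 6 SD on >= 10% of columns)
#' @param missing_fraction fraction of feature cells set missing
#' @param seed integer seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 90, n_features = 120,
                        informative = NULL, noise_sd = NULL,
                        r2_true = c(pcl5 = 0.35, phq9 = 0.30,
                                    beck = 0.50, conclusion = 0.50),
                        collinear_pairs = NULL,
                        outlier_fraction = 0.07,
                        missing_fraction = 0.02,
                        seed = 1L) {
  check_scalar(n_subjects, "n_subjects", lower = 4)
  check_scalar(n_features, "n_features", lower = 1)
  check_scalar(outlier_fraction, "outlier_fraction", lower = 0, upper = 1)
  check_scalar(missing_fraction, "missing_fraction", lower = 0, upper = 1)
  if (is.null(informative)) {
    # disjoint blocks of 5 unit-beta features per target
    informative <- list()
    for (k in seq_along(TARGET_NAMES)) {
      idx <- ((k - 1L) * 5L + 1L):(k * 5L)
      idx <- idx[idx <= n_features]
      informative[[TARGET_NAMES[k]]] <-
        list(features = idx, betas = rep(1, length(idx)))
    }
  }
  for (tn in TARGET_NAMES) {
    inf <- informative[[tn]]
    if (is.null(inf)) {
      informative[[tn]] <- list(features = integer(0), betas = numeric(0))
      next
    }
    stopifnot(length(inf$features) == length(inf$betas),
              all(is.finite(inf$betas)))
    if (length(inf$features) && max(inf$features) > n_features) {
      stop("informative feature index exceeds n_features", call. = FALSE)
    }
  }
  if (!is.null(collinear_pairs)) {
    stopifnot(is.data.frame(collinear_pairs),
              all(c("i", "j", "rho") %in% names(collinear_pairs)))
    if (any(abs(collinear_pairs$rho) >= 1)) {
      stop("|rho| must be < 1", call. = FALSE)
    }
    if (any(collinear_pairs$i == collinear_pairs$j) ||
        anyDuplicated(collinear_pairs$j) ||
        any(collinear_pairs$j %in% collinear_pairs$i)) {
      stop("collinear pairs overlap inconsistently: each j must be a ",
           "fresh column and distinct from its i", call. = FALSE)
    }
    if (any(collinear_pairs$i > n_features | collinear_pairs$j > n_features)) {
      stop("collinear pair index exceeds n_features", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_features = as.integer(n_features),
                 informative = informative, noise_sd = noise_sd,
                 r2_true = r2_true, collinear_pairs = collinear_pairs,
                 outlier_fraction = outlier_fraction,
                 missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# analytic covariance of the feature vector implied by the spec
cohort_feature_cov <- function(spec) {
  p <- spec$n_features
  S <- diag(p)
  cp <- spec$collinear_pairs
  if (!is.null(cp)) {
    for (r in seq_len(nrow(cp))) {
      S[cp$i[r], cp$j[r]] <- S[cp$j[r], cp$i[r]] <- cp$rho[r]
    }
  }
  S
}

#' Generate the synthetic cohort tables
#'
#' Base features are standard Gaussian; collinear pairs are planted at the
#' requested correlation; each target is `sum(beta_j * f_j) + eps` with
#' Gaussian noise. The population R-squared
#' `Var(sum beta f) / (Var(sum beta f) + noise_sd^2)` is reported in the
#' ground truth. Targets are computed from the clean features; outlier
#' corruption and missingness are applied to the feature table afterwards,
#' so planted outliers genuinely disrupt a naive fit. The fourth target is
#' discretised to 1-4 by quartile cut of its latent continuous score.
#'
#' @param spec a [cohort_spec()]
#' @return list with `features` (data.frame, `subject_id` + F columns),
#'   `targets` (data.frame, `subject_id` + four target columns) and
#'   `ground_truth` (list: per-target informative sets, betas, noise SDs,
#'   `r2_true`, outlier rows, missing cell count, collinear pairs)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  p <- spec$n_features
  Sig <- cohort_feature_cov(spec)

  out <- with_seed(spec$seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    cp <- spec$collinear_pairs
    if (!is.null(cp)) {
      for (r in seq_len(nrow(cp))) {
        i <- cp$i[r]; j <- cp$j[r]; rho <- cp$rho[r]
        X[, j] <- rho * X[, i] + sqrt(1 - rho^2) * X[, j]
      }
    }

    noise <- spec$noise_sd
    targets <- matrix(NA_real_, n, length(TARGET_NAMES),
                      dimnames = list(NULL, TARGET_NAMES))
    r2_true <- stats::setNames(numeric(length(TARGET_NAMES)), TARGET_NAMES)
    noise_used <- stats::setNames(numeric(length(TARGET_NAMES)), TARGET_NAMES)
    for (tn in TARGET_NAMES) {
      inf <- spec$informative[[tn]]
      if (length(inf$features)) {
        b <- numeric(p)
        b[inf$features] <- inf$betas
        v_signal <- drop(t(b) %*% Sig %*% b)
        lin <- drop(X %*% b)
      } else {
        v_signal <- 0
        lin <- numeric(n)
      }
      sd_eps <- if (!is.null(noise) && !is.na(noise[tn])) {
        as.numeric(noise[tn])
      } else if (v_signal > 0) {
        r2 <- spec$r2_true[[tn]]
        sqrt(v_signal * (1 - r2) / r2)
      } else {
        1
      }
      noise_used[tn] <- sd_eps
      r2_true[tn] <- if (v_signal == 0) 0 else
        v_signal / (v_signal + sd_eps^2)
      targets[, tn] <- lin + stats::rnorm(n, 0, sd_eps)
    }
    # ordinal psychologist's conclusion: quartile cut of the latent score
    qs <- stats::quantile(targets[, "conclusion"], c(0.25, 0.5, 0.75))
    targets[, "conclusion"] <-
      findInterval(targets[, "conclusion"], qs) + 1

    n_out <- floor(spec$outlier_fraction * n + 1e-9)
    outlier_rows <- if (n_out > 0) sort(sample.int(n, n_out)) else integer(0)
    n_cols_shift <- max(ceiling(0.15 * p), 1L)
    for (r in outlier_rows) {
      cols <- sample.int(p, n_cols_shift)
      X[r, cols] <- X[r, cols] + sample(c(-8, 8), n_cols_shift,
                                        replace = TRUE)
    }

    n_miss <- floor(spec$missing_fraction * n * p + 1e-9)
    if (n_miss > 0) {
      cells <- sample.int(n * p, n_miss)
      X[cells] <- NA_real_
    }
    list(X = X, targets = targets, r2_true = r2_true,
         noise_used = noise_used, outlier_rows = outlier_rows,
         n_missing = n_miss)
  })

  fnames <- sprintf("F%03d", seq_len(p))
  features <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         out$X, check.names = FALSE)
  names(features)[-1L] <- fnames
  targets <- data.frame(subject_id = features$subject_id,
                        out$targets, check.names = FALSE)
  gt <- list(
    informative = lapply(spec$informative, function(inf) {
      list(features = fnames[inf$features], betas = inf$betas)
    }),
    noise_sd = as.list(out$noise_used),
    r2_true = as.list(out$r2_true),
    outlier_rows = out$outlier_rows,
    n_missing_cells = out$n_missing,
    collinear_pairs = spec$collinear_pairs,
    seed = spec$seed)
  list(features = features, targets = targets, ground_truth = gt)
}

#' Write cohort ground truth as JSON
#' @param cohort result of [generate_cohort()]
#' @param path file path
#' @export
write_ground_truth_json <- function(cohort, path) {
  jsonlite::write_json(cohort$ground_truth, path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
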