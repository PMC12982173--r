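# Feature and target transformers for the selection pipeline. Every
# transformer is fitted on training data only and then applied to both
# sides of the split; target transformers carry an exact inverse so that
# predictions can be scored on the original target scale.

yj_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[neg] <- -((-x[neg] + 1)^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

yj_inverse <- function(z, lambda) {
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  neg <- !is.na(z) & z < 0
  if (abs(lambda) > 1e-10) {
    base <- pmax(lambda * z[pos] + 1, .Machine$double.eps)
    out[pos] <- base^(1 / lambda) - 1
  } else {
    out[pos] <- expm1(z[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    base <- pmax(1 - (2 - lambda) * z[neg], .Machine$double.eps)
    out[neg] <- 1 - base^(1 / (2 - lambda))
  } else {
    out[neg] <- -expm1(-z[neg])
  }
  out[is.na(z)] <- NA_real_
  out
}

yj_loglik <- function(x, lambda) {
  z <- yj_transform(x, lambda)
  n <- length(x)
  v <- stats::var(z) * (n - 1) / n
  if (!is.finite(v) || v <= 0) return(-Inf)
  -n / 2 * log(v) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

fit_yeo_johnson <- function(x) {
  x <- x[!is.na(x)]
  opt <- stats::optimize(function(l) yj_loglik(x, l),
                         interval = c(-5, 5), maximum = TRUE)
  opt$maximum
}

bc_transform <- function(y, lambda) {
  if (abs(lambda) > 1e-10) (y^lambda - 1) / lambda else log(y)
}

bc_inverse <- function(z, lambda) {
  if (abs(lambda) > 1e-10) {
    pmax(lambda * z + 1, .Machine$double.eps)^(1 / lambda)
  } else {
    exp(z)
  }
}

fit_box_cox <- function(y) {
  y <- y[!is.na(y)]
  ll <- function(lambda) {
    z <- bc_transform(y, lambda)
    n <- length(y)
    v <- stats::var(z) * (n - 1) / n
    if (!is.finite(v) || v <= 0) return(-Inf)
    -n / 2 * log(v) + (lambda - 1) * sum(log(y))
  }
  stats::optimize(ll, interval = c(-5, 5), maximum = TRUE)$maximum
}

#' Fit a feature transformer on training columns
#'
#' Methods: `"none"` (identity), `"quantile"` (empirical CDF mapped to a
#' standard normal, interpolated between training quantiles, clipped at
#' the tails), `"yeo-johnson"` (per-column maximum-likelihood lambda).
#'
#' @param X training feature matrix (numeric; NAs passed through)
#' @param method transformer name
#' @return object of class `feature_transformer`; apply with
#'   [apply_feature_transformer()]
#' @export
fit_feature_transformer <- function(X, method = c("none", "quantile",
                                                  "yeo-johnson")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  fit <- switch(method,
    none = NULL,
    quantile = lapply(seq_len(ncol(X)), function(j) {
      sort(X[!is.na(X[, j]), j])
    }),
    `yeo-johnson` = vapply(seq_len(ncol(X)), function(j) {
      fit_yeo_johnson(X[, j])
    }, numeric(1)))
  structure(list(method = method, fit = fit, p = ncol(X),
                 cols = colnames(X)),
            class = "feature_transformer")
}

#' @rdname fit_feature_transformer
#' @param ft a fitted `feature_transformer`
#' @export
apply_feature_transformer <- function(ft, X) {
  stopifnot(inherits(ft, "feature_transformer"))
  X <- as.matrix(X)
  if (ft$method == "none") return(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    if (ft$method == "quantile") {
      sx <- ft$fit[[j]]
      n <- length(sx)
      if (n < 2L || sx[1L] == sx[n]) { out[, j] <- 0; next }
      pr <- (seq_len(n) - 0.5) / n
      p <- stats::approx(sx, pr, xout = X[, j], rule = 2,
                         ties = mean)$y
      eps <- 1 / (4 * n)
      out[, j] <- stats::qnorm(pmin(pmax(p, eps), 1 - eps))
    } else {
      out[, j] <- yj_transform(X[, j], ft$fit[[j]])
    }
  }
  out
}

#' Fit a target transformer on the training target
#'
#' Methods: `"none"`, `"box-cox"` (positive targets only; the caller is
#' expected to skip the cell otherwise) and `"yeo-johnson"`. The returned
#' object carries `transform` and `inverse` closures.
#'
#' @param y numeric training target
#' @param method transformer name
#' @return object of class `target_transformer`
#' @export
fit_target_transformer <- function(y, method = c("none", "box-cox",
                                                 "yeo-johnson")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (method == "none") {
    tf <- identity; inv <- identity; lambda <- NA_real_
  } else if (method == "box-cox") {
    if (any(y[!is.na(y)] <= 0)) {
      stop("box-cox requires a strictly positive target", call. = FALSE)
    }
    lambda <- fit_box_cox(y)
    tf <- function(v) bc_transform(v, lambda)
    inv <- function(z) bc_inverse(z, lambda)
  } else {
    lambda <- fit_yeo_johnson(y)
    tf <- function(v) yj_transform(v, lambda)
    inv <- function(z) yj_inverse(z, lambda)
  }
  structure(list(method = method, lambda = lambda, transform = tf,
                 inverse = inv),
            class = "target_transformer")
}
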