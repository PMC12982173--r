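# Robustness diagnostic for composite indices: a Huber M-estimate of
# location is compared with the plain mean; a large discrepancy flags a
# distribution whose centre is being dragged by heavy tails.

#' Huber robustness check of a cohort index
#'
#' Computes the Huber M-estimate of location (tuning constant 1.345,
#' iteratively reweighted with MAD scale to a 1e-8 tolerance) and flags
#' the index as robust when the estimate and the arithmetic mean differ
#' by no more than a quarter of the (robust) spread. The spread in the
#' threshold is the MAD: using the plain SD would let gross outliers
#' inflate their own tolerance, so a heavily contaminated index could
#' never be flagged.
#'
#' @param index_values numeric vector of cohort index values (>= 10)
#' @param k Huber tuning constant (default 1.345)
#' @param tol convergence tolerance (default 1e-8)
#' @return list: `robust` flag, `huber_location`, `mean`, `delta`
#'   (absolute difference), `spread` (MAD used in the threshold), `sd`,
#'   `iterations`
#' @export
huber_robustness <- function(index_values, k = 1.345, tol = 1e-8) {
  x <- as.numeric(index_values)
  x <- x[!is.na(x)]
  if (length(x) < 10L) {
    stop("huber_robustness needs at least 10 values", call. = FALSE)
  }
  m <- mean(x)
  s_mad <- stats::mad(x)
  if (s_mad == 0) {
    # degenerate spread: fall back to the median as location
    mu <- stats::median(x)
    delta <- abs(mu - m)
    return(list(robust = delta <= 0, huber_location = mu, mean = m,
                delta = delta, spread = s_mad, sd = stats::sd(x),
                iterations = 0L))
  }
  mu <- stats::median(x)
  it <- 0L
  repeat {
    it <- it + 1L
    u <- (x - mu) / s_mad
    w <- pmin(1, k / pmax(abs(u), .Machine$double.eps))
    mu_new <- sum(w * x) / sum(w)
    if (abs(mu_new - mu) < tol || it >= 500L) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  delta <- abs(mu - m)
  list(robust = delta <= 0.25 * s_mad,
       huber_location = mu, mean = m, delta = delta, spread = s_mad,
       sd = stats::sd(x), iterations = it)
}
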