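# R-peak detection: FFT band-pass, squared-derivative envelope, adaptive
# (scale-invariant) threshold, 250 ms refractory period.

# zero-phase band-pass via the frequency domain; adequate for offline
# records of moderate length
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

moving_avg <- function(x, k) {
  k <- max(1L, as.integer(k))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2L)) -> y
  y[is.na(y)] <- 0
  y
}

#' Detect R peaks in one ECG lead
#'
#' Band-passes the lead to 5-25 Hz, squares its first difference into an
#' energy envelope, smooths it over 80 ms, and picks envelope maxima above
#' an adaptive threshold (a fixed fraction of a high quantile of the
#' envelope, hence invariant to overall signal gain), enforcing a 250 ms
#' refractory period. Peak positions are refined to the extremum of the
#' band-passed signal magnitude.
#'
#' @param record an [ecg_record()]
#' @param lead lead label to use (default "II")
#' @return strictly increasing integer sample indices of R peaks
#' @export
detect_r_peaks <- function(record, lead = "II") {
  stopifnot(inherits(record, "ecg_record"))
  if (!lead %in% record$lead_names) {
    stop("lead '", lead, "' not present; available: ",
         paste(record$lead_names, collapse = ", "), call. = FALSE)
  }
  fs <- record$sampling_rate
  x <- record$samples[, lead]
  if (length(x) < 2 * fs) {
    stop("record too short for R detection on lead '", lead,
         "' (need >= 2 s)", call. = FALSE)
  }
  if (max(x) - min(x) < .Machine$double.eps * 100) {
    stop("flat signal on lead '", lead, "': cannot detect R peaks",
         call. = FALSE)
  }
  xf <- fft_bandpass(x, fs, 5, 25)
  env <- c(0, diff(xf))^2
  env <- moving_avg(env, round(0.08 * fs))
  thr <- 0.20 * as.numeric(stats::quantile(env, 0.995))
  if (thr <= 0) {
    stop("no QRS energy found on lead '", lead, "'", call. = FALSE)
  }
  above <- which(env > thr)
  if (!length(above)) {
    stop("no samples above threshold on lead '", lead, "'", call. = FALSE)
  }
  refractory <- round(0.25 * fs)
  # group supra-threshold samples into bursts separated by > refractory
  breaks <- which(diff(above) > refractory)
  grp_start <- c(1L, breaks + 1L)
  grp_end <- c(breaks, length(above))
  half <- round(0.08 * fs)
  n <- length(x)
  peaks <- vapply(seq_along(grp_start), function(g) {
    idx <- above[grp_start[g]:grp_end[g]]
    centre <- idx[which.max(env[idx])]
    lo <- max(1L, centre - half)
    hi <- min(n, centre + half)
    win <- lo:hi
    win[which.max(abs(xf[win]))]
  }, integer(1))
  peaks <- sort(unique(peaks))
  # final refractory pass: keep the stronger of any pair too close
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    for (i in 2:length(peaks)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (peaks[i] - peaks[prev] < refractory) {
        if (abs(xf[peaks[i]]) > abs(xf[peaks[prev]])) {
          keep[prev] <- FALSE
        } else {
          keep[i] <- FALSE
        }
      }
    }
    peaks <- peaks[keep]
  }
  peaks
}
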