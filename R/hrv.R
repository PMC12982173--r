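# Heart rate variability metrics: time domain, Welch spectra of the
# interpolated tachogram, detrended fluctuation analysis, and the
# histogram/autocorrelation-based psycho-emotional indices.

#' Time-domain HRV metrics
#'
#' SDNN is the population SD of the RR series; successive differences are
#' signed; RMSSD is the root mean of their squares; SDSD their population
#' SD; pNN50 the percentage of differences strictly exceeding 50 ms.
#'
#' @param rr numeric RR intervals in ms (>= 3 values)
#' @return named list: `sdnn`, `rmssd`, `sdsd` (ms), `pnn50` (percent)
#' @export
hrv_time <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) < 3L) {
    stop("hrv_time needs at least 3 intervals", call. = FALSE)
  }
  d <- diff(rr)
  list(sdnn = pop_sd(rr),
       rmssd = sqrt(mean(d^2)),
       sdsd = pop_sd(d),
       pnn50 = 100 * sum(abs(d) > 50) / length(d))
}

# Welch periodogram with Hann window; returns data.frame(freq, psd).
# PSD is scaled so that sum(psd) * df equals the signal's mean power.
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  u <- sum(w^2)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    acc <- acc + Mod(X)^2 / (fs * u)
  }
  p <- acc / length(starts)
  half <- floor(nperseg / 2) + 1L
  psd <- p[seq_len(half)]
  # one-sided: double everything except DC (and Nyquist when present)
  dbl <- 2:(half - if (nperseg %% 2 == 0) 1L else 0L)
  psd[dbl] <- 2 * psd[dbl]
  data.frame(freq = (seq_len(half) - 1L) * fs / nperseg, psd = psd)
}

#' Frequency-domain HRV metrics from the interpolated tachogram
#'
#' The tachogram (RR against cumulative beat time) is cubic-interpolated
#' to a uniform 4 Hz grid and linearly detrended; the spectrum is a Welch
#' periodogram (64 s segments, 50% overlap, Hann window). LF is power in
#' 0.04-0.15 Hz, HF in 0.15-0.40 Hz, both in ms^2. The coherence ratio is
#' the power inside a +/- 0.015 Hz window around the tallest spectral peak
#' within 0.04-0.26 Hz, divided by the remaining power in 0.0033-0.40 Hz.
#'
#' @param rr numeric RR intervals in ms (>= 64, spanning >= one 64 s
#'   Welch segment)
#' @param resample_hz uniform grid rate (default 4 Hz)
#' @return named list: `lf`, `hf` (ms^2), `lf_hf`, `coherence_ratio`, and
#'   the `spectrum` data.frame
#' @export
hrv_freq <- function(rr, resample_hz = 4) {
  rr <- as.numeric(rr)
  if (length(rr) < 64L) {
    stop("hrv_freq needs at least 64 intervals", call. = FALSE)
  }
  t <- cumsum(rr) / 1000
  nperseg <- as.integer(64 * resample_hz)
  if (t[length(t)] - t[1L] < 64) {
    stop("series too short for one 64 s Welch segment", call. = FALSE)
  }
  grid <- seq(t[1L], t[length(t)], by = 1 / resample_hz)
  if (length(grid) < nperseg) {
    stop("series too short for one 64 s Welch segment", call. = FALSE)
  }
  y <- stats::spline(t, rr, xout = grid)$y
  y <- stats::residuals(stats::lm.fit(cbind(1, grid), y))
  sp <- welch_psd(y, fs = resample_hz, nperseg = nperseg)
  df <- sp$freq[2L] - sp$freq[1L]
  band <- function(lo, hi, lo_open = FALSE) {
    sel <- if (lo_open) sp$freq > lo & sp$freq <= hi else
      sp$freq >= lo & sp$freq < hi
    sum(sp$psd[sel]) * df
  }
  lf <- band(0.04, 0.15)
  hf <- sum(sp$psd[sp$freq >= 0.15 & sp$freq <= 0.40]) * df

  sel_peak <- sp$freq >= 0.04 & sp$freq <= 0.26
  coher <- NA_real_
  if (any(sel_peak)) {
    fpk <- sp$freq[sel_peak][which.max(sp$psd[sel_peak])]
    in_win <- abs(sp$freq - fpk) <= 0.015
    tot_sel <- sp$freq >= 0.0033 & sp$freq <= 0.40
    peak_pow <- sum(sp$psd[in_win & tot_sel]) * df
    rest <- sum(sp$psd[tot_sel & !in_win]) * df
    coher <- if (rest > 0) peak_pow / rest else NA_real_
  }
  list(lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_,
       coherence_ratio = coher, spectrum = sp)
}

#' Short-term scaling exponent via detrended fluctuation analysis
#'
#' Standard DFA: integrate the mean-centred series, split into
#' non-overlapping boxes of size 4 to 16 beats, remove a linear trend per
#' box, and take the least-squares slope of log fluctuation against log
#' box size.
#'
#' @param rr numeric RR intervals in ms (>= 100)
#' @param box_sizes integer box sizes (default 4:16, the alpha-1 range)
#' @return scaling exponent alpha-1 (dimensionless)
#' @export
hrv_dfa <- function(rr, box_sizes = 4:16) {
  rr <- as.numeric(rr)
  if (length(rr) < 100L) {
    stop("hrv_dfa needs at least 100 intervals", call. = FALSE)
  }
  y <- cumsum(rr - mean(rr))
  n <- length(y)
  fluct <- vapply(box_sizes, function(b) {
    nb <- n %/% b
    idx <- seq_len(nb * b)
    res2 <- 0
    tloc <- seq_len(b)
    X <- cbind(1, tloc)
    for (k in seq_len(nb)) {
      seg <- y[((k - 1L) * b + 1L):(k * b)]
      r <- stats::residuals(stats::lm.fit(X, seg))
      res2 <- res2 + sum(r^2)
    }
    sqrt(res2 / (nb * b))
  }, numeric(1))
  keep <- fluct > 0
  stats::coef(stats::lm.fit(cbind(1, log(box_sizes[keep])),
                            log(fluct[keep])))[2L]
}

#' Psycho-emotional HRV indices
#'
#' The Baevsky stress index is `AMo / (2 * Mo * MxDMn)` from an RR
#' histogram with 50 ms bins centred on multiples of 50 ms: AMo is the
#' modal bin share in percent, Mo the modal bin centre in seconds, MxDMn
#' the RR range in seconds. The coherence-based (McCraty-style) score is
#' the `coherence_ratio` of [hrv_freq()] (missing when the series is too
#' short for a spectrum). The Mashin index has no fixed published formula
#' here; the default is the lag-1 autocorrelation of the linearly
#' detrended RR series and can be replaced via `mashin_fun`.
#'
#' @param rr numeric RR intervals in ms (>= 30)
#' @param mashin_fun optional function(rr) -> numeric scalar overriding
#'   the default Mashin index
#' @return named list: `baevsky_si`, `mashin_index`, `mccraty_index`
#' @export
psycho_indices <- function(rr, mashin_fun = NULL) {
  rr <- as.numeric(rr)
  if (length(rr) < 30L) {
    stop("psycho_indices needs at least 30 intervals", call. = FALSE)
  }
  list(baevsky_si = baevsky_si(rr),
       mashin_index = if (is.null(mashin_fun)) mashin_default(rr) else
         mashin_fun(rr),
       mccraty_index = tryCatch(hrv_freq(rr)$coherence_ratio,
                                error = function(e) NA_real_))
}

# Baevsky stress index; exported separately so small worked examples
# (short series) remain checkable by hand.
#' @rdname psycho_indices
#' @export
baevsky_si <- function(rr) {
  rr <- as.numeric(rr)
  mxdmn <- (max(rr) - min(rr)) / 1000
  if (mxdmn == 0) {
    warning("zero RR range: Baevsky SI undefined", call. = FALSE)
    return(NA_real_)
  }
  centres <- round(rr / 50) * 50  # bins [c - 25, c + 25) around 50 ms grid
  tab <- table(centres)
  amo <- 100 * max(tab) / length(rr)
  mo <- as.numeric(names(tab)[which.max(tab)]) / 1000
  amo / (2 * mo * mxdmn)
}

mashin_default <- function(rr) {
  n <- length(rr)
  z <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), rr))
  a <- z[-n]; b <- z[-1L]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
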