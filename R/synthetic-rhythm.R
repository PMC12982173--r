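#' Rhythm specification for synthetic RR-interval series
#'
#' Describes a sinus rhythm as a mean RR interval plus two deterministic
#' sinusoidal modulations — a 0.1 Hz component standing in for baroreflex
#' (low-frequency) activity and a 0.25 Hz component standing in for
#' respiratory sinus arrhythmia (high-frequency) — plus white Gaussian
#' jitter. This is the generating model behind every synthetic HRV series
#' in the package.
#'
#' @param mean_rr mean RR interval in ms (> 200)
#' @param sd_rr   nominal overall RR SD in ms (bookkeeping only; the
#'   realised SD follows from the amplitudes and `noise_sd`)
#' @param lf_amp  amplitude of the 0.1 Hz modulation, ms
#' @param hf_amp  amplitude of the 0.25 Hz modulation, ms
#' @param noise_sd SD of the additive white jitter, ms
#' @param n_beats number of beats to generate (>= 2)
#' @param seed    integer seed; generation is deterministic given the spec
#' @return an object of class `rhythm_spec`
#' @export
rhythm_spec <- function(mean_rr = 900, sd_rr = 50, lf_amp = 25, hf_amp = 25,
                        noise_sd = 15, n_beats = 300, seed = 1L) {
  check_scalar(mean_rr, "mean_rr", lower = 200 + 1e-9)
  check_scalar(sd_rr, "sd_rr", lower = 0)
  check_scalar(lf_amp, "lf_amp", lower = 0)
  check_scalar(hf_amp, "hf_amp", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(n_beats, "n_beats", lower = 2)
  structure(list(mean_rr = mean_rr, sd_rr = sd_rr, lf_amp = lf_amp,
                 hf_amp = hf_amp, noise_sd = noise_sd,
                 n_beats = as.integer(n_beats), seed = as.integer(seed)),
            class = "rhythm_spec")
}

#' Generate a synthetic RR-interval series
#'
#' Interval k is
#' `mean_rr + lf_amp * sin(2*pi*0.1*t_k) + hf_amp * sin(2*pi*0.25*t_k) + e_k`
#' where `t_k` is the cumulative time (s) at the start of beat k (t_1 = 0)
#' and `e_k ~ N(0, noise_sd^2)`. Cumulative time uses the modulated
#' intervals themselves, so beat times and intervals are self-consistent.
#'
#' @param spec a [rhythm_spec()]
#' @return numeric vector of RR intervals in ms, class `rr_series`, with
#'   attribute `beat_times_s` (onset time of each interval in seconds)
#' @export
generate_rr_series <- function(spec) {
  if (!inherits(spec, "rhythm_spec")) spec <- do.call(rhythm_spec, spec)
  n <- spec$n_beats
  eps <- with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd))
  rr <- numeric(n)
  t <- numeric(n)
  tk <- 0
  for (k in seq_len(n)) {
    t[k] <- tk
    rr[k] <- spec$mean_rr +
      spec$lf_amp * sin(2 * pi * 0.10 * tk) +
      spec$hf_amp * sin(2 * pi * 0.25 * tk) +
      eps[k]
    if (rr[k] < 200) rr[k] <- 200  # physiological floor, keeps times monotone
    tk <- tk + rr[k] / 1000
  }
  structure(rr, beat_times_s = t, class = c("rr_series", "numeric"))
}

#' Read / write an RR series as a single-column CSV in ms
#' @param rr numeric RR intervals (ms)
#' @param path file path
#' @return `read_rr_csv` returns a numeric vector of intervals in ms.
#' @export
write_rr_csv <- function(rr, path) {
  utils::write.csv(data.frame(rr_ms = as.numeric(rr)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(df[[1L]])
}
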