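# Synthetic six-lead ECG generator: each beat is a static sum of Gaussian
# waves on leads I and II; the four remaining limb leads are derived by
# the standard lead algebra, which gives the extractor tests a free
# invariant (III = II - I exactly, up to float noise).

# A Gaussian drops to 5% of its peak at center +/- sigma * sqrt(2 ln 20).
# Wave onset/offset ground truth is defined at that crossing so the
# 5%-threshold delineator can be validated against analytic truth.
GAUSS_5PCT <- sqrt(2 * log(20))

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

#' Beat morphology specification for the synthetic ECG
#'
#' Defines one beat as five Gaussian waves (P, Q, R, S, T) per primary
#' lead (I and II), each with a signed amplitude in microvolts, a center
#' offset from the R peak in seconds, and a Gaussian width (sigma) in
#' seconds. Wave centers default to positions consistent with the
#' requested PQ, QT and QRS interval targets, where a wave's onset and
#' offset are its 5% amplitude crossings.
#'
#' @param pq PQ interval target, s (P onset to QRS onset)
#' @param qt QT interval target, s (QRS onset to T offset)
#' @param qrs QRS duration target, s (QRS onset to QRS offset)
#' @param sampling_rate sampling rate in Hz (>= 250)
#' @param amplitudes named list with elements `I` and `II`, each a named
#'   numeric vector over P, Q, R, S, T in microvolts
#' @param widths named numeric vector of Gaussian sigmas (s) over
#'   P, Q, R, S, T, shared by both primary leads
#' @param centers optional named numeric vector of wave centers (s,
#'   relative to R); when NULL they are derived from the interval targets
#' @return an object of class `beat_spec`
#' @export
beat_spec <- function(pq = 0.16, qt = 0.38, qrs = 0.10,
                      sampling_rate = 500,
                      amplitudes = list(
                        I  = c(P = 100, Q = -60,  R = 800,  S = -120, T = 250),
                        II = c(P = 150, Q = -80,  R = 1000, S = -150, T = 300)),
                      widths = c(P = 0.020, Q = 0.006, R = 0.008,
                                 S = 0.008, T = 0.050),
                      centers = NULL) {
  check_scalar(pq, "pq", lower = 1e-6)
  check_scalar(qt, "qt", lower = 1e-6)
  check_scalar(qrs, "qrs", lower = 1e-6)
  check_scalar(sampling_rate, "sampling_rate", lower = 250)
  stopifnot(is.list(amplitudes), all(c("I", "II") %in% names(amplitudes)))
  for (ld in c("I", "II")) {
    if (!all(WAVE_NAMES %in% names(amplitudes[[ld]]))) {
      stop("amplitudes$", ld, " must name all of P, Q, R, S, T",
           call. = FALSE)
    }
  }
  if (!all(WAVE_NAMES %in% names(widths)) || any(widths[WAVE_NAMES] <= 0)) {
    stop("widths must be positive for all of P, Q, R, S, T", call. = FALSE)
  }
  widths <- widths[WAVE_NAMES]
  if (is.null(centers)) {
    # place QRS asymmetrically around R (onset 45%, offset 55% of QRS)
    qrs_on <- -0.45 * qrs
    qrs_off <- 0.55 * qrs
    centers <- c(
      P = qrs_on - pq + GAUSS_5PCT * widths[["P"]],
      Q = qrs_on + GAUSS_5PCT * widths[["Q"]],
      R = 0,
      S = qrs_off - GAUSS_5PCT * widths[["S"]],
      T = qrs_on + qt - GAUSS_5PCT * widths[["T"]])
  }
  centers <- centers[WAVE_NAMES]
  if (pq >= qt) stop("PQ must be shorter than QT", call. = FALSE)
  p_off <- centers[["P"]] + GAUSS_5PCT * widths[["P"]]
  q_on <- centers[["Q"]] - GAUSS_5PCT * widths[["Q"]]
  t_on <- centers[["T"]] - GAUSS_5PCT * widths[["T"]]
  s_off <- centers[["S"]] + GAUSS_5PCT * widths[["S"]]
  if (!(p_off <= q_on && s_off <= t_on)) {
    stop("wave centers/widths inconsistent: P must end before QRS onset ",
         "and T must start after QRS offset", call. = FALSE)
  }
  # every wave's 5% support must span at least 5 samples
  if (2 * GAUSS_5PCT * min(widths) * sampling_rate < 5) {
    stop("sampling_rate too low to resolve the narrowest wave ",
         "(need >= 5 samples across its width)", call. = FALSE)
  }
  structure(list(pq = pq, qt = qt, qrs = qrs,
                 sampling_rate = sampling_rate,
                 amplitudes = lapply(amplitudes[c("I", "II")],
                                     function(a) a[WAVE_NAMES]),
                 widths = widths, centers = centers),
            class = "beat_spec")
}

#' Multi-lead ECG record container
#'
#' @param samples numeric matrix, time x lead, in microvolts
#' @param sampling_rate Hz (> 0)
#' @param lead_names character labels, subset of I, II, III, aVR, aVL, aVF
#' @return object of class `ecg_record`
#' @export
ecg_record <- function(samples, sampling_rate,
                       lead_names = colnames(samples)) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 1L) stop("need at least one lead", call. = FALSE)
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  if (is.null(lead_names) || length(lead_names) != ncol(samples)) {
    stop("lead_names must label every column", call. = FALSE)
  }
  known <- c("I", "II", "III", "aVR", "aVL", "aVF")
  if (!all(lead_names %in% known)) {
    stop("unknown lead label(s): ",
         paste(setdiff(lead_names, known), collapse = ", "), call. = FALSE)
  }
  colnames(samples) <- lead_names
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 lead_names = lead_names),
            class = "ecg_record")
}

#' Generate a six-lead synthetic ECG record with ground-truth fiducials
#'
#' Renders the [beat_spec()] template at beat onsets spaced by a
#' [generate_rr_series()] rhythm on leads I and II, then derives the
#' remaining limb leads sample-wise: `III = II - I`, `aVR = -(I + II)/2`,
#' `aVL = I - II/2`, `aVF = II - I/2`.
#'
#' @param beat a [beat_spec()]
#' @param rhythm a [rhythm_spec()]
#' @param noise_uV SD of additive white measurement noise in microvolts
#'   (applied independently per primary lead; derived leads inherit it
#'   through the algebra)
#' @return list of class `synth_ecg` with elements `record`
#'   ([ecg_record()]), `fiducials` (data.frame: beat, lead, wave,
#'   onset_s/peak_s/offset_s and sample indices, amplitude_uV), `rr_ms`,
#'   and `r_peak_samples`
#' @export
generate_ecg_record <- function(beat, rhythm, noise_uV = 0) {
  stopifnot(inherits(beat, "beat_spec"), inherits(rhythm, "rhythm_spec"))
  check_scalar(noise_uV, "noise_uV", lower = 0)
  fs <- beat$sampling_rate
  rr <- generate_rr_series(rhythm)
  beat_t <- attr(rr, "beat_times_s")
  pad_start <- 0.45
  pad_end <- 0.70
  r_times <- pad_start + beat_t
  dur <- r_times[length(r_times)] + pad_end
  n <- floor(dur * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs

  render_lead <- function(amps) {
    y <- numeric(n)
    for (k in seq_along(r_times)) {
      for (w in WAVE_NAMES) {
        a <- amps[[w]]
        if (a == 0) next
        mu <- r_times[k] + beat$centers[[w]]
        s <- beat$widths[[w]]
        lo <- max(1L, floor((mu - 5 * s) * fs) + 1L)
        hi <- min(n, ceiling((mu + 5 * s) * fs) + 1L)
        idx <- lo:hi
        y[idx] <- y[idx] + a * exp(-((tt[idx] - mu)^2) / (2 * s^2))
      }
    }
    y
  }
  lead_I <- render_lead(beat$amplitudes$I)
  lead_II <- render_lead(beat$amplitudes$II)
  if (noise_uV > 0) {
    nz <- with_seed(substream_seed(rhythm$seed, "ecg-noise"),
                    matrix(stats::rnorm(2L * n, 0, noise_uV), ncol = 2L))
    lead_I <- lead_I + nz[, 1L]
    lead_II <- lead_II + nz[, 2L]
  }
  samples <- cbind(I = lead_I, II = lead_II,
                   III = lead_II - lead_I,
                   aVR = -(lead_I + lead_II) / 2,
                   aVL = lead_I - lead_II / 2,
                   aVF = lead_II - lead_I / 2)
  rec <- ecg_record(samples, fs)

  fid <- do.call(rbind, lapply(seq_along(r_times), function(k) {
    do.call(rbind, lapply(c("I", "II"), function(ld) {
      a <- beat$amplitudes[[ld]]
      data.frame(
        beat = k, lead = ld, wave = WAVE_NAMES,
        onset_s = r_times[k] + beat$centers - GAUSS_5PCT * beat$widths,
        peak_s = r_times[k] + beat$centers,
        offset_s = r_times[k] + beat$centers + GAUSS_5PCT * beat$widths,
        amplitude_uV = as.numeric(a),
        row.names = NULL)
    }))
  }))
  fid$onset_sample <- round(fid$onset_s * fs) + 1L
  fid$peak_sample <- round(fid$peak_s * fs) + 1L
  fid$offset_sample <- round(fid$offset_s * fs) + 1L

  structure(list(record = rec, fiducials = fid, rr_ms = as.numeric(rr),
                 r_peak_samples = round(r_times * fs) + 1L,
                 beat = beat, rhythm = rhythm),
            class = "synth_ecg")
}

#' Read / write an ECG record as CSV (time column + one column per lead)
#' @param record an [ecg_record()]
#' @param path file path
#' @return `read_ecg_csv` returns an [ecg_record()].
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  n <- nrow(record$samples)
  df <- data.frame(time_s = (seq_len(n) - 1L) / record$sampling_rate)
  for (ld in record$lead_names) df[[ld]] <- record$samples[, ld]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("ECG CSV needs a time column plus >= 1 lead",
                          call. = FALSE)
  t <- df[[1L]]
  fs <- 1 / stats::median(diff(t))
  ecg_record(as.matrix(df[, -1L, drop = FALSE]), sampling_rate = fs,
             lead_names = names(df)[-1L])
}

#' Write ground-truth fiducials to CSV
#' @param synth a `synth_ecg` object from [generate_ecg_record()]
#' @param path file path
#' @export
write_fiducials_csv <- function(synth, path) {
  stopifnot(inherits(synth, "synth_ecg"))
  utils::write.csv(synth$fiducials, path, row.names = FALSE)
  invisible(path)
}
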