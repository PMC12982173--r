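# Median-beat wave delineation and amplitude-time measurement.
#
# All per-beat morphology is measured on a median beat per lead (robust to
# noise on short records). Wave onsets/offsets are located by threshold
# crossing at 5% of each wave's peak-to-baseline excursion; the baseline
# is the median of the PQ segment; the J-point is the QRS offset.

# fraction of the R excursion below which a Q/S/P/T deflection is treated
# as absent (amplitude 0, duration 0)
ABSENT_WAVE_FRAC <- 0.02

# walk outward from a wave peak until |rel| drops below 5% of the wave's
# excursion or the deflection reverses sign (the boundary with an
# adjacent opposite wave can be a steep zero crossing that no sample
# lands inside); returns the last index still on the wave
walk_crossing <- function(rel, from, step, bound, excursion) {
  thr <- 0.05 * abs(excursion)
  sgn <- sign(excursion)
  i <- from
  while (i != bound) {
    nxt <- rel[i + step]
    if (abs(nxt) < thr || sgn * nxt <= 0) break
    i <- i + step
  }
  i
}

delineate_lead <- function(medbeat, centre, fs) {
  n <- length(medbeat)
  sec <- function(s) max(1L, min(n, centre + round(s * fs)))

  locate <- function(baseline) {
    rel <- medbeat - baseline
    # R: extremum near the aligned centre (sign-free: derived leads flip)
    rwin <- sec(-0.05):sec(0.05)
    r_idx <- rwin[which.max(abs(rel[rwin]))]
    r_amp <- rel[r_idx]
    sgn <- sign(r_amp)
    absf <- ABSENT_WAVE_FRAC * abs(r_amp)

    # Q: opposite-sign extremum shortly before R
    qwin <- sec(-0.07):max(sec(-0.07), r_idx - max(1L, round(0.006 * fs)))
    q_idx <- qwin[which.max(-sgn * rel[qwin])]
    q_amp <- rel[q_idx]
    q_present <- (-sgn * q_amp) > absf
    # S: opposite-sign extremum shortly after R
    swin <- min(sec(0.09), r_idx + max(1L, round(0.006 * fs))):sec(0.09)
    s_idx <- swin[which.max(-sgn * rel[swin])]
    s_amp <- rel[s_idx]
    s_present <- (-sgn * s_amp) > absf

    qrs_on <- if (q_present) {
      walk_crossing(rel, q_idx, -1L, sec(-0.10), q_amp)
    } else {
      walk_crossing(rel, r_idx, -1L, sec(-0.10), r_amp)
    }
    qrs_off <- if (s_present) {
      walk_crossing(rel, s_idx, +1L, sec(0.12), s_amp)
    } else {
      walk_crossing(rel, r_idx, +1L, sec(0.12), r_amp)
    }
    list(rel = rel, r_idx = r_idx, r_amp = r_amp,
         q_idx = q_idx, q_amp = q_amp, q_present = q_present,
         s_idx = s_idx, s_amp = s_amp, s_present = s_present,
         qrs_on = qrs_on, qrs_off = qrs_off)
  }

  # pass 1: provisional baseline; pass 2: PQ-segment baseline
  st <- locate(stats::median(medbeat))
  pq_lo <- max(1L, st$qrs_on - round(0.045 * fs))
  pq_hi <- max(pq_lo, st$qrs_on - max(1L, round(0.004 * fs)))
  baseline <- stats::median(medbeat[pq_lo:pq_hi])
  st <- locate(baseline)
  rel <- st$rel
  absf <- ABSENT_WAVE_FRAC * abs(st$r_amp)

  # P: largest |excursion| in the window before QRS onset
  p_lo <- max(1L, st$qrs_on - round(0.28 * fs))
  p_hi <- max(p_lo, st$qrs_on - max(1L, round(0.010 * fs)))
  pwin <- p_lo:p_hi
  p_idx <- pwin[which.max(abs(rel[pwin]))]
  p_amp <- rel[p_idx]
  p_present <- abs(p_amp) > absf

  # T: largest |excursion| after the QRS (walk may extend slightly
  # earlier than the peak-search window, down to just past the J point)
  t_lo <- min(n, st$qrs_off + round(0.04 * fs))
  t_hi <- min(n, st$qrs_off + round(0.45 * fs))
  t_walk_lo <- min(n, st$qrs_off + max(1L, round(0.008 * fs)))
  twin <- t_lo:t_hi
  t_idx <- twin[which.max(abs(rel[twin]))]
  t_amp <- rel[t_idx]
  t_present <- abs(t_amp) > absf

  mk <- function(present, idx, amp, lo_bound, hi_bound) {
    if (!present) {
      return(c(onset = idx, peak = idx, offset = idx, amplitude = 0,
               present = 0))
    }
    on <- walk_crossing(rel, idx, -1L, lo_bound, amp)
    off <- walk_crossing(rel, idx, +1L, hi_bound, amp)
    c(onset = on, peak = idx, offset = off, amplitude = amp, present = 1)
  }
  waves <- rbind(
    P = mk(p_present, p_idx, p_amp, p_lo, p_hi),
    Q = mk(st$q_present, st$q_idx, st$q_amp, sec(-0.10), st$r_idx),
    R = mk(TRUE, st$r_idx, st$r_amp, st$qrs_on, st$qrs_off),
    S = mk(st$s_present, st$s_idx, st$s_amp, st$r_idx, sec(0.12)),
    T = mk(t_present, t_idx, t_amp, t_walk_lo, t_hi))
  waves <- as.data.frame(waves)
  waves$wave <- rownames(waves)
  rownames(waves) <- NULL

  list(waves = waves[, c("wave", "onset", "peak", "offset", "amplitude",
                         "present")],
       baseline = baseline, qrs_on = st$qrs_on, qrs_off = st$qrs_off,
       j_point = st$qrs_off)
}

#' Delineate ECG waves on a median beat per lead
#'
#' Builds a median beat per lead from windows around the detected R peaks
#' (-0.40 s to +0.60 s), then locates P, Q, R, S, T onsets, peaks and
#' offsets by 5% threshold crossing of each wave's baseline-relative
#' excursion. The baseline is the median of the PQ segment; the J-point is
#' the QRS offset. Deflections smaller than 2% of the R excursion are
#' reported as absent (amplitude 0, duration 0).
#'
#' @param record an [ecg_record()]
#' @param rpeaks integer sample indices from [detect_r_peaks()]
#' @return object of class `fiducial_set`: per-lead wave tables (indices
#'   into the median beat and seconds relative to the R peak), baselines,
#'   J-points, the median beats and the R peak list
#' @export
delineate <- function(record, rpeaks) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(rpeaks) < 2L) {
    stop("delineation needs at least 2 beats", call. = FALSE)
  }
  fs <- record$sampling_rate
  pre <- round(0.40 * fs)
  post <- round(0.60 * fs)
  n <- nrow(record$samples)
  ok <- rpeaks - pre >= 1L & rpeaks + post <= n
  if (sum(ok) < 2L) {
    stop("fewer than 2 beats with a full median-beat window", call. = FALSE)
  }
  rp <- rpeaks[ok]
  win_len <- pre + post + 1L
  per_lead <- list()
  medbeats <- matrix(NA_real_, win_len, length(record$lead_names),
                     dimnames = list(NULL, record$lead_names))
  for (ld in record$lead_names) {
    x <- record$samples[, ld]
    beats <- vapply(rp, function(r) x[(r - pre):(r + post)],
                    numeric(win_len))
    mb <- apply(beats, 1L, stats::median)
    medbeats[, ld] <- mb
    dl <- delineate_lead(mb, centre = pre + 1L, fs = fs)
    w <- dl$waves
    w$onset_rel_s <- (w$onset - (pre + 1L)) / fs
    w$peak_rel_s <- (w$peak - (pre + 1L)) / fs
    w$offset_rel_s <- (w$offset - (pre + 1L)) / fs
    per_lead[[ld]] <- list(waves = w, baseline = dl$baseline,
                           qrs_on = dl$qrs_on, qrs_off = dl$qrs_off,
                           j_point = dl$j_point)
  }
  structure(list(rpeaks = rpeaks, used_rpeaks = rp, pre = pre, post = post,
                 sampling_rate = fs, median_beats = medbeats,
                 per_lead = per_lead),
            class = "fiducial_set")
}

#' Measure amplitude-time parameters from a delineated record
#'
#' Per lead: signed baseline-relative amplitudes of P, Q, R, S, T
#' (microvolts); durations of P, Q, QRS, PQ (P onset to QRS onset) and QT
#' (QRS onset to T offset) in seconds; trapezoidal areas of the P wave and
#' the QRS complex as integrals of |signal - baseline| over the wave span
#' (microvolt-seconds); and the J-point dislocation (baseline-relative
#' level at the QRS offset, microvolts).
#'
#' @param record the [ecg_record()] the fiducials came from
#' @param fiducials a `fiducial_set` from [delineate()]
#' @param leads leads to measure (default: all in the record)
#' @return long data.frame (lead, measure, value) with attribute
#'   `rr_mean_s` (mean RR in seconds from the R peak list)
#' @export
measure_waves <- function(record, fiducials, leads = record$lead_names) {
  stopifnot(inherits(record, "ecg_record"),
            inherits(fiducials, "fiducial_set"))
  missing_leads <- setdiff(leads, record$lead_names)
  if (length(missing_leads)) {
    stop("lead(s) not in record: ", paste(missing_leads, collapse = ", "),
         "; available: ", paste(record$lead_names, collapse = ", "),
         call. = FALSE)
  }
  fs <- fiducials$sampling_rate
  rows <- list()
  for (ld in leads) {
    pl <- fiducials$per_lead[[ld]]
    mb <- fiducials$median_beats[, ld]
    rel <- mb - pl$baseline
    w <- pl$waves
    rownames(w) <- w$wave
    dur <- function(wave) {
      if (w[wave, "present"] == 0) return(0)
      (w[wave, "offset"] - w[wave, "onset"]) / fs
    }
    area <- function(from, to) {
      idx <- from:to
      sum(diff(idx / fs) * (abs(rel[idx])[-1] + abs(rel[idx])[-length(idx)]) / 2)
    }
    qrs_dur <- (pl$qrs_off - pl$qrs_on) / fs
    pq <- if (w["P", "present"] == 1) (pl$qrs_on - w["P", "onset"]) / fs else NA_real_
    qt <- if (w["T", "present"] == 1) (w["T", "offset"] - pl$qrs_on) / fs else NA_real_
    p_area <- if (w["P", "present"] == 1) area(w["P", "onset"], w["P", "offset"]) else 0
    vals <- c(
      amplitude_P = w["P", "amplitude"], amplitude_Q = w["Q", "amplitude"],
      amplitude_R = w["R", "amplitude"], amplitude_S = w["S", "amplitude"],
      amplitude_T = w["T", "amplitude"],
      duration_P = dur("P"), duration_Q = dur("Q"),
      duration_QRS = qrs_dur, duration_PQ = pq, duration_QT = qt,
      area_P = p_area, area_QRS = area(pl$qrs_on, pl$qrs_off),
      j_point = rel[pl$j_point])
    rows[[ld]] <- data.frame(lead = ld, measure = names(vals),
                             value = as.numeric(vals), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "rr_mean_s") <-
    mean(diff(fiducials$rpeaks)) / fs
  out
}

#' Derive ratio and corrected-interval features from wave measurements
#'
#' Computes, per lead, Q/R, R/P and R/T as ratios of absolute amplitudes
#' and the P/QRS area ratio; plus the Macruz index
#' `P_duration / (PQ - P_duration)` and the Fridericia-corrected QT
#' `QTcF = QT / RR^(1/3)` (both from the `interval_lead`, default II).
#' Zero denominators yield missing values (never infinities) and are
#' reported via a message.
#'
#' @param measurements output of [measure_waves()]
#' @param rr_mean_s mean RR interval in seconds (defaults to the
#'   attribute carried by `measurements`)
#' @param interval_lead lead used for the interval-based indices
#' @return long data.frame (lead, measure, value); interval indices carry
#'   the `interval_lead` label
#' @export
derive_ratios <- function(measurements, rr_mean_s = NULL,
                          interval_lead = "II") {
  rr_mean_s <- rr_mean_s %||% attr(measurements, "rr_mean_s")
  get <- function(lead, meas) {
    v <- measurements$value[measurements$lead == lead &
                              measurements$measure == meas]
    if (!length(v)) NA_real_ else v
  }
  safe_ratio <- function(num, den, label) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) {
      message("ratio '", label, "': zero denominator, reported missing")
      return(NA_real_)
    }
    num / den
  }
  rows <- list()
  for (ld in unique(measurements$lead)) {
    aP <- abs(get(ld, "amplitude_P")); aQ <- abs(get(ld, "amplitude_Q"))
    aR <- abs(get(ld, "amplitude_R")); aT <- abs(get(ld, "amplitude_T"))
    vals <- c(
      ratio_QR = safe_ratio(aQ, aR, paste0("Q/R ", ld)),
      ratio_RP = safe_ratio(aR, aP, paste0("R/P ", ld)),
      ratio_RT = safe_ratio(aR, aT, paste0("R/T ", ld)),
      area_ratio_PQRS = safe_ratio(get(ld, "area_P"), get(ld, "area_QRS"),
                                   paste0("P/QRS area ", ld)))
    rows[[ld]] <- data.frame(lead = ld, measure = names(vals),
                             value = as.numeric(vals), row.names = NULL)
  }
  p_dur <- get(interval_lead, "duration_P")
  pq <- get(interval_lead, "duration_PQ")
  qt <- get(interval_lead, "duration_QT")
  macruz <- if (is.na(p_dur) || is.na(pq)) NA_real_ else
    safe_ratio(p_dur, pq - p_dur, "Macruz")
  qtcf <- if (is.na(qt) || is.na(rr_mean_s) || rr_mean_s <= 0) NA_real_ else
    qt / rr_mean_s^(1 / 3)
  rows[["intervals"]] <- data.frame(
    lead = interval_lead, measure = c("macruz", "qtcf"),
    value = c(macruz, qtcf), row.names = NULL)
  do.call(rbind, rows)
}
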