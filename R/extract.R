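# One-subject feature extraction: runs detection, delineation,
# measurement, ratios and all HRV metrics, and assembles a single named
# row whose column labels follow the conventional published wording
# ("Amplitude Q-wave (uV) (lead AvR)", "PNN50, %", ...), so cohort tables
# built from signals are directly comparable with association tables.

paper_lead <- function(ld) {
  c(I = "I", II = "II", III = "III",
    aVR = "AvR", aVL = "AvL", aVF = "AvF")[[ld]]
}

#' Extract the full ECG/HRV feature vector for one subject
#'
#' @param record an [ecg_record()] (any subset of the six limb leads)
#' @param rr optional RR series in ms; when NULL it is derived from the
#'   detected R peaks
#' @param lead_for_rpeaks lead used for R detection (default "II")
#' @return one-row data.frame of named features (missing values allowed)
#' @export
extract_features <- function(record, rr = NULL, lead_for_rpeaks = "II") {
  rpeaks <- detect_r_peaks(record, lead_for_rpeaks)
  fid <- delineate(record, rpeaks)
  meas <- measure_waves(record, fid)
  if (is.null(rr)) {
    rr <- diff(rpeaks) / record$sampling_rate * 1000
  }
  rat <- derive_ratios(meas, rr_mean_s = mean(rr) / 1000)

  uv <- "\u03bcV"  # micro sign, matches published column labels
  out <- list()
  g <- function(tbl, lead, m) {
    v <- tbl$value[tbl$lead == lead & tbl$measure == m]
    if (!length(v)) NA_real_ else v
  }
  for (ld in record$lead_names) {
    pl <- paper_lead(ld)
    out[[sprintf("Amplitude P-wave (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "amplitude_P")
    out[[sprintf("Amplitude Q-wave (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "amplitude_Q")
    out[[sprintf("Amplitude R-wave (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "amplitude_R")
    out[[sprintf("Amplitude S-wave (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "amplitude_S")
    out[[sprintf("Amplitude T-wave (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "amplitude_T")
    out[[sprintf("Amplitude Q/R ratio (lead %s)", pl)]] <- g(rat, ld, "ratio_QR")
    out[[sprintf("Amplitude ratio R/P (lead %s)", pl)]] <- g(rat, ld, "ratio_RP")
    out[[sprintf("R/T amplitude ratio (lead %s)", pl)]] <- g(rat, ld, "ratio_RT")
    out[[sprintf("Area ratio P/QRS (lead %s)", pl)]] <- g(rat, ld, "area_ratio_PQRS")
    out[[sprintf("P-wave area (%s*sec) (lead %s)", uv, pl)]] <- g(meas, ld, "area_P")
    out[[sprintf("QRS area (%s*sec) (lead %s)", uv, pl)]] <- g(meas, ld, "area_QRS")
    out[[sprintf("J-point dislocation (%s) (lead %s)", uv, pl)]] <- g(meas, ld, "j_point")
  }
  # interval features from lead II (or the first available lead)
  il <- if ("II" %in% record$lead_names) "II" else record$lead_names[1L]
  out[["Duration of P-wave (sec)"]] <- g(meas, il, "duration_P")
  out[["Q duration (sec)"]] <- g(meas, il, "duration_Q")
  out[["QRS duration (sec)"]] <- g(meas, il, "duration_QRS")
  out[["Duration PQ (sec)"]] <- g(meas, il, "duration_PQ")
  out[["QT duration (sec)"]] <- g(meas, il, "duration_QT")
  out[["QTcF duration (sec)"]] <- g(rat, il, "qtcf")
  out[["Macruz index P/(PQ-P)"]] <- g(rat, il, "macruz")

  ht <- hrv_time(rr)
  out[["SDNN, ms"]] <- ht$sdnn
  out[["RMSSD, ms"]] <- ht$rmssd
  out[["SDSD, ms"]] <- ht$sdsd
  out[["PNN50, %"]] <- ht$pnn50
  hf <- tryCatch(hrv_freq(rr), error = function(e) NULL)
  out[["LF"]] <- if (is.null(hf)) NA_real_ else hf$lf
  out[["HF"]] <- if (is.null(hf)) NA_real_ else hf$hf
  out[["LF/HF ratio"]] <- if (is.null(hf)) NA_real_ else hf$lf_hf
  out[["Detrended Fluctuation Analysis (DFA) of HRV"]] <-
    tryCatch(hrv_dfa(rr), error = function(e) NA_real_)
  pi_ <- tryCatch(psycho_indices(rr), error = function(e)
    list(baevsky_si = NA_real_, mashin_index = NA_real_,
         mccraty_index = NA_real_))
  out[["Baevsky stress index"]] <- pi_$baevsky_si
  out[["Mashin psycho-emotional index"]] <- pi_$mashin_index
  out[["McCraty psycho-emotional index"]] <- pi_$mccraty_index
  out[["Mean RR (ms)"]] <- mean(rr)
  out[["Heart rate (bpm)"]] <- 60000 / mean(rr)

  as.data.frame(out, check.names = FALSE)
}
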