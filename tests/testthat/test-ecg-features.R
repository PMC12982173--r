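# R detection, delineation, wave measurement and derived ratios.

test_that("detect_r_peaks finds every beat of a clean record", {
  se <- noiseless_synth()
  rp <- detect_r_peaks(se$record, "II")
  expect_true(abs(length(rp) - length(se$r_peak_samples)) <= 1)
  matched <- vapply(se$r_peak_samples, function(r) min(abs(rp - r)),
                    numeric(1))
  expect_true(all(matched <= 0.02 * se$record$sampling_rate))
})

test_that("detect_r_peaks is gain-invariant and rejects degenerate input", {
  se <- noiseless_synth()
  rp1 <- detect_r_peaks(se$record, "II")
  rec2 <- ecg_record(se$record$samples * 2, se$record$sampling_rate)
  expect_identical(detect_r_peaks(rec2, "II"), rp1)

  flat <- ecg_record(matrix(0, 2000, 1, dimnames = list(NULL, "II")), 500)
  expect_error(detect_r_peaks(flat, "II"), "flat")
  expect_error(detect_r_peaks(se$record, "V1"), "not present")
  shorty <- ecg_record(se$record$samples[1:400, , drop = FALSE], 500)
  expect_error(detect_r_peaks(shorty, "II"), "short")
})

test_that("delineation recovers wave boundaries within 10 ms on clean data", {
  se <- noiseless_synth()
  fid <- delineate(se$record, detect_r_peaks(se$record, "II"))
  r_time <- (se$r_peak_samples[1] - 1) / se$record$sampling_rate
  tr <- se$fiducials[se$fiducials$beat == 1 & se$fiducials$lead == "II", ]
  w <- fid$per_lead$II$waves
  for (wv in c("P", "Q", "R", "S", "T")) {
    truth <- tr[tr$wave == wv, ]
    est <- w[w$wave == wv, ]
    expect_lt(abs((truth$onset_s - r_time) - est$onset_rel_s), 0.010,
              label = paste(wv, "onset error"))
    expect_lt(abs((truth$offset_s - r_time) - est$offset_rel_s), 0.010,
              label = paste(wv, "offset error"))
  }
})

test_that("an absent Q wave reports zero amplitude and duration", {
  amps <- list(I = c(P = 100, Q = 0, R = 800, S = -120, T = 250),
               II = c(P = 150, Q = 0, R = 1000, S = -150, T = 300))
  se <- generate_ecg_record(
    beat_spec(amplitudes = amps),
    rhythm_spec(mean_rr = 1000, lf_amp = 0, hf_amp = 0, noise_sd = 0,
                n_beats = 8, seed = 2))
  fid <- delineate(se$record, detect_r_peaks(se$record, "II"))
  m <- measure_waves(se$record, fid, leads = "II")
  expect_identical(m$value[m$measure == "amplitude_Q"], 0)
  expect_identical(m$value[m$measure == "duration_Q"], 0)
})

test_that("5 uV of white noise moves median-beat fiducials by < 10 ms", {
  se0 <- noiseless_synth()
  bs <- beat_spec()
  rs <- rhythm_spec(mean_rr = 1000, sd_rr = 0, lf_amp = 0, hf_amp = 0,
                    noise_sd = 0, n_beats = 10, seed = 3)
  se1 <- generate_ecg_record(bs, rs, noise_uV = 5)
  f0 <- delineate(se0$record, detect_r_peaks(se0$record, "II"))
  f1 <- delineate(se1$record, detect_r_peaks(se1$record, "II"))
  w0 <- f0$per_lead$II$waves
  w1 <- f1$per_lead$II$waves
  expect_lt(max(abs(w0$onset_rel_s - w1$onset_rel_s),
                abs(w0$offset_rel_s - w1$offset_rel_s)), 0.010)
})

test_that("delineate requires at least two usable beats", {
  se <- noiseless_synth()
  expect_error(delineate(se$record, se$r_peak_samples[1]), "2 beats")
})

test_that("measured amplitudes hit the template within 2%", {
  se <- noiseless_synth()
  bs <- beat_spec()
  fid <- delineate(se$record, detect_r_peaks(se$record, "II"))
  for (ld in c("I", "II")) {
    m <- measure_waves(se$record, fid, leads = ld)
    for (wv in c("P", "Q", "R", "S", "T")) {
      truth <- bs$amplitudes[[ld]][[wv]]
      est <- m$value[m$measure == paste0("amplitude_", wv)]
      expect_lt(abs(est - truth), 0.02 * abs(truth),
                label = paste("amplitude", wv, "lead", ld))
    }
  }
  expect_error(measure_waves(se$record, fid, leads = "V6"), "available")
})

test_that("measured amplitudes respect the lead algebra", {
  se <- noiseless_synth()
  fid <- delineate(se$record, detect_r_peaks(se$record, "II"))
  m <- measure_waves(se$record, fid)
  g <- function(ld, ms) m$value[m$lead == ld & m$measure == ms]
  for (wv in c("P", "R", "T")) {
    ms <- paste0("amplitude_", wv)
    lhs <- g("aVF", ms)
    rhs <- g("II", ms) - g("I", ms) / 2
    expect_lt(abs(lhs - rhs), 0.05 * abs(rhs),
              label = paste("aVF algebra for", wv))
  }
})

test_that("trapezoidal areas are exact on a rectangular pulse", {
  # rectangle of height h over width w: trapezoid rule is exact
  fs <- 500
  h <- 200; w <- 0.08
  n <- 41L
  x <- c(rep(0, 10), rep(h, w * fs + 1), rep(0, 10))
  idx <- 11L:(11L + w * fs)
  area <- sum(diff(idx / fs) * (abs(x[idx])[-1] +
                                  abs(x[idx])[-length(idx)]) / 2)
  expect_equal(area, h * w, tolerance = 1e-12)
})

test_that("derive_ratios matches the hand-computed worked examples", {
  meas <- data.frame(
    lead = "II",
    measure = c("amplitude_P", "amplitude_Q", "amplitude_R", "amplitude_S",
                "amplitude_T", "duration_P", "duration_PQ", "duration_QT",
                "area_P", "area_QRS"),
    value = c(150, -80, 1000, -150, 300, 0.10, 0.16, 0.36, 8, 30))
  r <- derive_ratios(meas, rr_mean_s = 0.729)
  g <- function(ms) r$value[r$measure == ms]
  expect_equal(g("macruz"), 0.10 / 0.06, tolerance = 1e-9)  # 1.667
  expect_equal(g("qtcf"), 0.40, tolerance = 1e-9)           # 0.729^(1/3) = 0.9
  expect_equal(g("ratio_QR"), 80 / 1000, tolerance = 1e-12)
  expect_equal(g("ratio_RP"), 1000 / 150, tolerance = 1e-12)
  # unit cube root: QT 0.40 at RR 1.0 s
  r2 <- derive_ratios(transform(meas, value = replace(value,
                                                      measure == "duration_QT",
                                                      0.40)),
                      rr_mean_s = 1.0)
  expect_equal(r2$value[r2$measure == "qtcf"], 0.40, tolerance = 1e-12)
})

test_that("zero denominators become missing values, not infinities", {
  meas <- data.frame(
    lead = "II",
    measure = c("amplitude_P", "amplitude_Q", "amplitude_R",
                "amplitude_T", "duration_P", "duration_PQ",
                "area_P", "area_QRS"),
    value = c(0, -80, 1000, 300, 0.16, 0.16, 8, 30))
  expect_message(r <- derive_ratios(meas, rr_mean_s = 1), "missing")
  expect_true(is.na(r$value[r$measure == "ratio_RP"]))
  expect_true(is.na(r$value[r$measure == "macruz"]))
  expect_false(any(is.infinite(r$value), na.rm = TRUE))
})

test_that("full extraction produces the published column labels", {
  se <- noiseless_synth()
  fv <- extract_features(se$record, rr = se$rr_ms)
  expect_true(all(c("Amplitude Q-wave (\u03bcV) (lead AvR)", "PNN50, %",
                    "QTcF duration (sec)", "Macruz index P/(PQ-P)",
                    "SDSD, ms", "Baevsky stress index") %in% names(fv)))
  expect_identical(nrow(fv), 1L)
})
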