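# Synthetic RR series, ECG records and cohort tables.

test_that("generate_rr_series honours the degenerate and deterministic contracts", {
  spec <- rhythm_spec(mean_rr = 1000, sd_rr = 0, lf_amp = 0, hf_amp = 0,
                      noise_sd = 0, n_beats = 50, seed = 1)
  rr <- generate_rr_series(spec)
  expect_length(as.numeric(rr), 50L)
  expect_true(all(rr == 1000))

  spec2 <- rhythm_spec(mean_rr = 800, noise_sd = 30, n_beats = 100, seed = 7)
  expect_identical(as.numeric(generate_rr_series(spec2)),
                   as.numeric(generate_rr_series(spec2)))
  expect_error(rhythm_spec(mean_rr = 150), "mean_rr")
  expect_error(rhythm_spec(n_beats = 1), "n_beats")
  expect_error(rhythm_spec(lf_amp = -1), "lf_amp")
})

test_that("generated RR jitter matches the generating SD (Monte Carlo)", {
  sds <- vapply(1:20, function(s) {
    rr <- generate_rr_series(rhythm_spec(mean_rr = 800, lf_amp = 0,
                                         hf_amp = 0, noise_sd = 30,
                                         n_beats = 300, seed = s))
    stats::sd(rr)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 30), 5)
})

test_that("sinusoidal modulation lands in the intended spectral band", {
  rr_hf <- generate_rr_series(rhythm_spec(mean_rr = 900, lf_amp = 0,
                                          hf_amp = 40, noise_sd = 0,
                                          n_beats = 200, seed = 2))
  h <- hrv_freq(rr_hf)
  expect_gt(h$hf / (h$lf + h$hf), 0.95)
})

test_that("derived limb leads satisfy the lead algebra exactly", {
  se <- noiseless_synth()
  s <- se$record$samples
  scale_uv <- max(abs(s))
  expect_lt(max(abs(s[, "III"] - (s[, "II"] - s[, "I"]))), 1e-9 * scale_uv)
  expect_lt(max(abs(s[, "aVR"] + (s[, "I"] + s[, "II"]) / 2)), 1e-9 * scale_uv)
  expect_lt(max(abs(s[, "aVL"] - (s[, "I"] - s[, "II"] / 2))), 1e-9 * scale_uv)
  expect_lt(max(abs(s[, "aVF"] - (s[, "II"] - s[, "I"] / 2))), 1e-9 * scale_uv)
})

test_that("ground-truth fiducials evaluate the analytic template", {
  se <- noiseless_synth()
  fid <- se$fiducials
  r2 <- fid[fid$beat == 2 & fid$lead == "II" & fid$wave == "R", ]
  v <- se$record$samples[r2$peak_sample, "II"]
  expect_lt(abs(v - 1000) / 1000, 0.01)
  # 10 s at 60 bpm -> 10 +/- 1 beats
  expect_true(abs(length(se$r_peak_samples) - 10) <= 1)
})

test_that("beat_spec validates geometry and sampling", {
  expect_error(beat_spec(sampling_rate = 100), "sampling_rate")
  expect_error(beat_spec(pq = 0.5, qt = 0.4), "PQ")
  expect_error(beat_spec(widths = c(P = 0.02, Q = -1, R = 0.008,
                                    S = 0.008, T = 0.05)), "widths")
  # narrowest wave resolvable: < 5 samples across its 5% support fails
  expect_error(beat_spec(sampling_rate = 250,
                         widths = c(P = 0.02, Q = 0.002, R = 0.008,
                                    S = 0.008, T = 0.05)),
               "resolve")
})

test_that("ECG CSV round-trip preserves the record", {
  se <- noiseless_synth()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(se$record, path)
  rec2 <- read_ecg_csv(path)
  expect_equal(rec2$lead_names, se$record$lead_names)
  expect_equal(rec2$sampling_rate, se$record$sampling_rate, tolerance = 1e-6)
  expect_equal(rec2$samples[, "II"], se$record$samples[, "II"],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("generate_cohort plants the advertised ground truth", {
  # no-signal target has R2_true 0
  ch0 <- null_cohort(1)
  expect_true(all(unlist(ch0$ground_truth$r2_true) == 0))
  expect_identical(sum(is.na(ch0$features[, -1])), 0L)
  expect_length(ch0$ground_truth$outlier_rows, 0L)

  # beta = (1, 1) on unit-variance independent features, noise sqrt(2)
  sp <- cohort_spec(n_subjects = 50, n_features = 10,
                    informative = list(beck = list(features = c(1, 2),
                                                   betas = c(1, 1))),
                    noise_sd = c(beck = sqrt(2)),
                    outlier_fraction = 0, missing_fraction = 0, seed = 4)
  ch <- generate_cohort(sp)
  expect_equal(ch$ground_truth$r2_true$beck, 0.5, tolerance = 1e-12)

  # determinism
  ch2 <- generate_cohort(sp)
  expect_identical(ch$features, ch2$features)
  expect_identical(ch$targets, ch2$targets)

  # conclusion is an ordinal 1-4
  expect_true(all(ch$targets$conclusion %in% 1:4))
})

test_that("planted collinear pairs reach the requested correlation", {
  rhos <- vapply(1:20, function(s) {
    sp <- cohort_spec(n_subjects = 90, n_features = 20,
                      collinear_pairs = data.frame(i = 1, j = 10,
                                                   rho = 0.9),
                      outlier_fraction = 0, missing_fraction = 0,
                      seed = s)
    ch <- generate_cohort(sp)
    stats::cor(ch$features$F001, ch$features$F010)
  }, numeric(1))
  expect_true(all(abs(rhos - 0.9) < 0.1))
})

test_that("oracle OLS on the informative set approaches R2_true at large n", {
  sp <- cohort_spec(n_subjects = 5000, n_features = 20,
                    informative = list(beck = list(features = 1:5,
                                                   betas = rep(1, 5))),
                    r2_true = c(pcl5 = 0.3, phq9 = 0.3, beck = 0.5,
                                conclusion = 0.3),
                    outlier_fraction = 0, missing_fraction = 0, seed = 9)
  ch <- generate_cohort(sp)
  X <- as.matrix(ch$features[, sprintf("F%03d", 1:5)])
  fit <- stats::lm.fit(cbind(1, X), ch$targets$beck)
  r2 <- 1 - sum(fit$residuals^2) /
    sum((ch$targets$beck - mean(ch$targets$beck))^2)
  expect_lt(abs(r2 - 0.5), 0.05)
})

test_that("cohort spec rejects inconsistent collinear pairs and bad indices", {
  expect_error(cohort_spec(collinear_pairs = data.frame(i = 1, j = 1,
                                                        rho = 0.5)),
               "overlap")
  expect_error(cohort_spec(collinear_pairs = data.frame(i = c(1, 2),
                                                        j = c(3, 3),
                                                        rho = 0.5)),
               "overlap")
  expect_error(cohort_spec(collinear_pairs = data.frame(i = 1, j = 2,
                                                        rho = 1.2)),
               "rho")
  expect_error(cohort_spec(n_features = 10,
                           informative = list(beck = list(features = 99,
                                                          betas = 1))),
               "exceeds")
})

test_that("outlier and missing planting follow the requested fractions", {
  sp <- cohort_spec(n_subjects = 90, n_features = 50,
                    outlier_fraction = 0.1, missing_fraction = 0.05,
                    seed = 12)
  ch <- generate_cohort(sp)
  expect_length(ch$ground_truth$outlier_rows, 9L)
  expect_identical(sum(is.na(ch$features[, -1])),
                   as.integer(floor(0.05 * 90 * 50)))
  # planted rows carry gross shifts: their max |z| is extreme
  X <- as.matrix(ch$features[, -1])
  rows <- ch$ground_truth$outlier_rows
  mx <- apply(abs(X[rows, , drop = FALSE]), 1, max, na.rm = TRUE)
  expect_true(all(mx > 4))
})
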