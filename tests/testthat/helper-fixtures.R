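# Shared fixtures, built in code and memoised for the whole run.

# noiseless 10-beat record at 60 bpm with the default beat template
noiseless_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_ecg_record(
        beat_spec(),
        rhythm_spec(mean_rr = 1000, sd_rr = 0, lf_amp = 0, hf_amp = 0,
                    noise_sd = 0, n_beats = 10, seed = 3))
    }
    cache
  }
})

# 1/f (pink) noise via spectral synthesis
pink_noise <- function(n, seed) {
  set.seed(seed)
  half <- n %/% 2
  amp <- c(0, 1 / sqrt(seq_len(half)))
  ph <- stats::runif(half + 1, 0, 2 * pi)
  m <- n - half - 1
  spec <- complex(modulus = c(amp, rev(amp[seq_len(m) + 1])),
                  argument = c(ph, -rev(ph[seq_len(m) + 1])))
  Re(stats::fft(spec, inverse = TRUE))
}

# clean planted cohort used by selection tests: 100 features, 5 planted
# unit-beta features for every target, population R2 = 0.5, no outliers
# or missing cells
clean_planted_cohort <- function(seed) {
  generate_cohort(cohort_spec(
    n_features = 100, outlier_fraction = 0, missing_fraction = 0,
    r2_true = c(pcl5 = 0.5, phq9 = 0.5, beck = 0.5, conclusion = 0.5),
    seed = seed))
}

# null cohort: no signal to any target
null_cohort <- function(seed, n_features = 100) {
  inf <- lapply(c(pcl5 = 1, phq9 = 1, beck = 1, conclusion = 1),
                function(i) list(features = integer(0),
                                 betas = numeric(0)))
  generate_cohort(cohort_spec(
    n_features = n_features, informative = inf,
    noise_sd = c(pcl5 = 1, phq9 = 1, beck = 1, conclusion = 1),
    outlier_fraction = 0, missing_fraction = 0, seed = seed))
}

# small fast selection config for unit tests
fast_config <- function(seed = 1L, ...) {
  selection_config(max_features = 6, feature_transformers = "none",
                   target_transformers = "none", seed = seed, ...)
}
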