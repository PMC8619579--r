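# Shared fixtures, generated in code. The default-parameter study used by the
# acceptance-level checks is built once per test run and memoized.

fixture_env <- new.env(parent = emptyenv())

# Default-condition study at the study's sampling rate, scaled to 60 s per
# condition so the whole suite stays fast; all generative parameters are the
# package defaults.
acceptance_study <- function() {
  if (is.null(fixture_env$study)) {
    cfg <- synthetic_config(n_subjects = 4, duration_s = 60,
                            mixing_seed = 101L, noise_seed = 202L)
    fixture_env$study <- generate_study(cfg)
  }
  fixture_env$study
}

acceptance_features <- function() {
  if (is.null(fixture_env$features)) {
    fixture_env$features <- extract_axis_features(acceptance_study(), "unmix")
  }
  fixture_env$features
}

# One-channel recording holding a given signal.
single_channel <- function(x, fs = 256) {
  recording(matrix(x, nrow = 1L), fs = fs, channel_labels = "ch1")
}

rms <- function(x) sqrt(mean(x^2))

# Steady-state portion of a filtered trace: drop one FIR group delay per edge.
steady <- function(x, lo, hi, fs = 256) {
  h <- aculatent:::design_bandpass(lo, hi, fs)
  L <- (length(h) - 1L) %/% 2L
  x[(L + 1L):(length(x) - L)]
}
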