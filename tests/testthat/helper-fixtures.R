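# In-code fixture builders shared across test files.

# Multichannel recording of pure sinusoids: freqs_hz per channel, optional
# per-channel phase offsets and amplitudes.
sine_recording <- function(freqs_hz, fs = 500, dur_s = 10, phases = 0,
                           amps = 1, onset_s = NULL, termination_s = NULL) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  m <- length(freqs_hz)
  phases <- rep_len(phases, m)
  amps <- rep_len(amps, m)
  dat <- t(vapply(seq_len(m), function(i) {
    amps[i] * cos(2 * pi * freqs_hz[i] * t + phases[i])
  }, numeric(length(t))))
  new_recording(dat, fs = fs, onset_s = onset_s,
                termination_s = termination_s)
}

noise_recording <- function(m = 4, fs = 500, dur_s = 10, seed = 7,
                            onset_s = NULL, termination_s = NULL) {
  set.seed(seed)
  new_recording(matrix(rnorm(m * round(dur_s * fs)), m), fs = fs,
                onset_s = onset_s, termination_s = termination_s)
}

# A hand-built period segmentation (for unit tests that do not need a
# recording behind it).
manual_segmentation <- function(periods, starts, ends, fs = 500) {
  structure(data.frame(period = periods, start_s = starts, end_s = ends,
                       stringsAsFactors = FALSE),
            class = c("period_segmentation", "data.frame"), fs = fs)
}

# A hand-built state sequence.
manual_states <- function(labels, centers_s) {
  structure(list(labels = labels, K = length(unique(labels)),
                 centroids = NULL, window_centers_s = centers_s),
            class = "state_sequence")
}

# Small, fast seizure fixture for smoke/pipeline tests (not the canonical
# geometry: fewer channels, shorter seizure, lower rate).
small_fixture <- function(seed = 1) {
  make_seizure_fixture(M = 8, fs = 500, seizure_s = 8, switch_s = 2,
                       seed = seed)
}

period_interval_test <- function(seg, period) {
  i <- match(period, seg$period)
  c(seg$start_s[i], seg$end_s[i])
}
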