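# Shared fixtures, built in code at test time.

# small fast cohort: reduced sampling rate and duration keep the full
# pipeline affordable while preserving every stage's semantics
small_config <- function(seed = 42, n_infants = 6, fs = 125,
                         duration_range = c(100, 140), ...) {
  synthetic_config(n_infants = n_infants, fs = fs,
                   duration_range = duration_range, seed = seed, ...)
}

# a tiny deterministic recording: sinusoids plus noise on 4 channels
toy_recording <- function(n_ch = 4, fs = 100, dur_s = 10, seed = 1,
                          labels = paste0("ch", seq_len(n_ch))) {
  set.seed(seed)
  n <- fs * dur_s
  t_ax <- seq_len(n) / fs
  data <- t(sapply(seq_len(n_ch), function(c) {
    5 * sin(2 * pi * 10 * t_ax + c) + rnorm(n, sd = 2)
  }))
  eeg_recording(data, fs = fs, labels = labels, infant_id = "toy")
}

# per-infant duration values from the published clean-duration table,
# mirrored by the packaged fixture CSV
table2_events <- function() {
  read_annotations(system.file("extdata", "table2_durations.csv",
                               package = "squirm"))
}

table2_printed <- function() {
  tibble::tribble(
    ~condition, ~mean_s, ~sd_s, ~n_contributing,
    "rest", 38.3, 14.7, 12L,
    "jaw", 10.3, 5.0, 6L,
    "hand", 23.6, 11.9, 8L,
    "arm", 12.2, 8.4, 10L,
    "foot", 27.3, 43.9, 4L,
    "leg", 22.2, 18.4, 10L
  )
}

# epoched_power built directly from a spectra matrix + noise, for cluster
# tests that do not need the signal-level pipeline
fake_epoched_power <- function(mean_mat, n_epochs, infant_id, condition,
                               freqs = seq_len(ncol(mean_mat)),
                               channels = rownames(mean_mat), sd = 0.1) {
  pow <- array(0, dim = c(n_epochs, nrow(mean_mat), ncol(mean_mat)))
  for (e in seq_len(n_epochs)) {
    pow[e, , ] <- pmax(mean_mat + matrix(rnorm(length(mean_mat), sd = sd),
                                         nrow(mean_mat)), 1e-6)
  }
  structure(
    list(pow = pow, freqs = freqs, infant_id = infant_id,
         condition = condition, channels = channels),
    class = "epoched_power"
  )
}

# paired spectra for n subjects on the full montage with iid normal noise
# and an optional mean shift added to the motion condition
null_paired_spectra <- function(n_sub, n_bins = 20, shift = NULL,
                                montage = build_montage()) {
  channels <- montage$label
  mk <- function(s, cond, delta) {
    base <- matrix(10, length(channels), n_bins,
                   dimnames = list(channels, seq_len(n_bins)))
    mean_mat <- base + (if (is.null(delta)) 0 else delta)
    fake_epoched_power(mean_mat + matrix(rnorm(length(base)),
                                         length(channels)),
                       n_epochs = 2, infant_id = s, condition = cond,
                       freqs = seq_len(n_bins), sd = 0.01)
  }
  subjects <- sprintf("s%02d", seq_len(n_sub))
  pair_spectra(
    motion = lapply(subjects, mk, cond = "arm", delta = shift),
    rest = lapply(subjects, mk, cond = "rest", delta = NULL)
  )
}
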