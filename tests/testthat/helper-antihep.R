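# Desk-scale simulation profile used throughout the tests: 16 channels at
# 160 Hz with native == analysis rate; down-sampling is exercised separately
# at the full 2048 -> 512 Hz ratio.
scaled_acq <- function(n_channels = 16, rate = 160) {
  acquisition_config(native_rate = rate, analysis_rate = rate,
                     n_channels = n_channels)
}

tiny_paradigm <- function(targets = 25) {
  paradigm_config(total_targets = targets)
}

# Bare recording container for hand-crafted signal matrices.
make_recording <- function(mat, srate, events = NULL, rpeaks = numeric()) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- default_montage(ncol(mat))
  }
  if (is.null(events)) {
    events <- tibble::tibble(onset_s = numeric(), is_target = logical())
  }
  structure(
    list(signals = mat, srate = srate, channels = colnames(mat),
         events = events, rpeaks = rpeaks, truth = NULL),
    class = "eeg_recording"
  )
}

# Bare averaged-ERP container for hand-crafted waveforms (times in ms).
make_erp <- function(mat, srate, pre_ms = 200, n_epochs = 1) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2")[
      seq_len(ncol(mat))]
  }
  structure(
    list(data = mat,
         times_ms = (seq_len(nrow(mat)) - 1 - round(pre_ms / 1000 * srate)) /
           srate * 1000,
         srate = srate, channels = colnames(mat),
         n_epochs = n_epochs, partition = "custom"),
    class = "eeg_erp"
  )
}
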