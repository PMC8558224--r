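#' Down-sample a recording
#'
#' Anti-alias filters and decimates every channel to `target_rate`. Integer
#' ratios use `signal::decimate()` (zero-phase IIR low-pass plus decimation);
#' rational ratios fall back to `signal::resample()` (polyphase FIR). Event
#' and R-peak times are stored in seconds and are therefore unchanged.
#'
#' @param recording An `eeg_recording`.
#' @param target_rate Target sampling rate in Hz (must not exceed the current
#'   rate).
#' @return The recording at `target_rate`.
#' @export
resample_recording <- function(recording, target_rate) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    stop("target_rate must be positive", call. = FALSE)
  }
  fs <- recording$srate
  if (target_rate > fs) {
    stop("target_rate cannot exceed the native rate", call. = FALSE)
  }
  if (target_rate == fs) {
    return(recording)
  }
  x <- recording$signals
  if (fs %% target_rate == 0) {
    q <- fs / target_rate
    out <- apply(x, 2, function(col) signal::decimate(col, q))
  } else {
    frac <- rational_ratio(target_rate / fs)
    out <- apply(x, 2, function(col) signal::resample(col, frac[1], frac[2]))
  }
  recording$signals <- `colnames<-`(as.matrix(out), recording$channels)
  recording$srate <- target_rate
  recording
}

rational_ratio <- function(r, max_den = 4096) {
  best <- c(1, 1)
  err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) {
      err <- e
      best <- c(p, q)
      if (e < 1e-12) break
    }
  }
  best
}

#' Apply a common average reference
#'
#' Subtracts the instantaneous mean over all channels from every channel, so
#' the channel sum is zero at every sample. Idempotent.
#'
#' @param recording An `eeg_recording` with at least two channels.
#' @return The re-referenced recording.
#' @export
apply_car <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (ncol(recording$signals) < 2) {
    stop("common average referencing needs at least 2 channels", call. = FALSE)
  }
  recording$signals <- recording$signals - rowMeans(recording$signals)
  recording$car <- TRUE
  recording
}

#' Flag epochs whose amplitude exceeds a threshold
#'
#' An epoch is rejected iff its maximum absolute amplitude over all channels
#' and samples strictly exceeds `threshold` ("exceeded" is read as strict:
#' a peak exactly at the threshold is kept). Operates on every channel in the
#' epoch, not only the analysis electrodes.
#'
#' @param epochs An `eeg_epochs` object.
#' @param threshold Rejection threshold in uV (default 100).
#' @return The epoch set with updated `kept`, `peak_uV` and `peak_channel`
#'   columns in `$info`; the rejection log is available via
#'   [rejection_log()].
#' @export
reject_epochs <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.numeric(threshold) || is.na(threshold)) {
    stop("threshold must be numeric", call. = FALSE)
  }
  n_ep <- dim(epochs$data)[3]
  if (is.na(n_ep) || n_ep == 0) {
    epochs$threshold <- threshold
    return(epochs)
  }
  peaks <- numeric(n_ep)
  peak_ch <- character(n_ep)
  for (i in seq_len(n_ep)) {
    a <- abs(epochs$data[, , i])
    j <- which.max(a)
    peaks[i] <- a[j]
    peak_ch[i] <- epochs$channels[(j - 1) %/% nrow(a) + 1]
  }
  epochs$info$peak_uV <- peaks
  epochs$info$peak_channel <- peak_ch
  epochs$info$kept <- peaks <= threshold
  epochs$threshold <- threshold
  epochs
}

#' Rejection log of an epoch set
#'
#' @param epochs An `eeg_epochs` object after [reject_epochs()].
#' @return Tibble with columns `epoch_id`, `kept`, `peak_uV`, `channel`.
#' @export
rejection_log <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  tibble::tibble(
    epoch_id = epochs$info$epoch_id,
    kept = epochs$info$kept,
    peak_uV = epochs$info$peak_uV,
    channel = epochs$info$peak_channel
  )
}
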