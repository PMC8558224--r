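#' Extract target-locked epochs from a recording
#'
#' Cuts a half-open `[-pre_ms, post_ms)` window around each target onset on
#' the recording's sampling grid, giving every epoch exactly
#' `(pre_ms + post_ms) / 1000 * srate` samples. Events too close to a
#' recording edge are skipped with a warning. The R-peak latencies falling
#' inside each epoch span are attached for later partitioning.
#'
#' @param recording An `eeg_recording` (typically down-sampled and
#'   re-referenced).
#' @param spec An [epoch_spec()].
#' @param events Optional event tibble; defaults to the recording's target
#'   events.
#' @return An object of class `eeg_epochs`: `data` (samples x channels x
#'   epochs array), `times_ms` (relative to onset), `srate`, `channels`,
#'   `spec` and an `info` tibble (`epoch_id`, `onset_s`,
#'   `rpeak_latencies_ms` list-column, `kept`, `label`).
#' @export
extract_epochs <- function(recording, spec = epoch_spec(), events = NULL) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "epoch_spec"))
  fs <- recording$srate
  if (is.null(events)) {
    events <- recording$events[recording$events$is_target, , drop = FALSE]
  }
  pre_n <- round(spec$pre_ms / 1000 * fs)
  post_n <- round(spec$post_ms / 1000 * fs)
  len <- pre_n + post_n
  n_total <- nrow(recording$signals)

  onset_idx <- round(events$onset_s * fs) + 1L
  first <- onset_idx - pre_n
  last <- onset_idx + post_n - 1L
  ok <- first >= 1L & last <= n_total
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge were skipped",
                    sum(!ok)), call. = FALSE)
  }
  onsets <- events$onset_s[ok]
  first <- first[ok]
  n_ep <- length(first)

  data <- array(0, dim = c(len, ncol(recording$signals), n_ep),
                dimnames = list(NULL, recording$channels, NULL))
  for (i in seq_len(n_ep)) {
    data[, , i] <- recording$signals[first[i]:(first[i] + len - 1L), ]
  }

  rlat <- lapply(onsets, function(on) {
    lat <- (recording$rpeaks - on) * 1000
    lat[lat >= -spec$pre_ms & lat < spec$post_ms]
  })

  info <- tibble::tibble(
    epoch_id = seq_len(n_ep),
    onset_s = onsets,
    rpeak_latencies_ms = rlat,
    kept = rep(TRUE, n_ep),
    peak_uV = rep(NA_real_, n_ep),
    peak_channel = rep(NA_character_, n_ep),
    label = rep(NA_character_, n_ep)
  )
  if (!is.null(recording$truth$targets) && nrow(recording$truth$targets) > 0) {
    m <- match(round(onsets, 9), round(recording$truth$targets$onset_s, 9))
    info$true_amplitude <- recording$truth$targets$amplitude[m]
    info$true_attenuated <- recording$truth$targets$attenuated[m]
  }

  structure(
    list(
      data = data,
      times_ms = (seq_len(len) - 1 - pre_n) / fs * 1000,
      srate = fs,
      channels = recording$channels,
      spec = spec,
      info = info,
      baseline_corrected = FALSE
    ),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz [%g, %g) ms; %d kept%s\n",
    dim(x$data)[3], dim(x$data)[2], dim(x$data)[1], x$srate,
    -x$spec$pre_ms, x$spec$post_ms, sum(x$info$kept),
    if (all(is.na(x$info$label))) "" else
      sprintf("; %d HEP / %d A-HEP", sum(x$info$label == "HEP", na.rm = TRUE),
              sum(x$info$label == "A-HEP", na.rm = TRUE))
  ))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean of the pre-stimulus segment
#' (times < 0), so the pre-stimulus mean becomes zero. Idempotent up to float
#' tolerance.
#'
#' @param epochs An `eeg_epochs` object.
#' @return The baseline-corrected epoch set.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  pre_idx <- which(epochs$times_ms < 0)
  if (length(pre_idx) == 0) {
    stop("epochs contain no pre-stimulus samples to use as baseline",
         call. = FALSE)
  }
  n_ep <- dim(epochs$data)[3]
  for (i in seq_len(n_ep)) {
    bl <- colMeans(epochs$data[pre_idx, , i, drop = FALSE])
    epochs$data[, , i] <- sweep(epochs$data[, , i, drop = FALSE][, , 1],
                                2, bl, `-`)
  }
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Average epochs into an ERP waveform
#'
#' Pointwise arithmetic mean over the selected kept epochs.
#'
#' @param epochs An `eeg_epochs` object.
#' @param subset Either a logical/integer epoch selector, a partition name
#'   (`"ERP_T"`, `"ERP_HEP"`, `"ERP_A-HEP"` — requires
#'   [partition_epochs()] first), or `NULL` for all kept epochs.
#' @return An object of class `eeg_erp`: `data` (samples x channels matrix),
#'   `times_ms`, `srate`, `channels`, `n_epochs`, `partition`.
#' @export
average_epochs <- function(epochs, subset = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  partition <- "custom"
  if (is.null(subset)) {
    mask <- epochs$info$kept
    partition <- "ERP_T"
  } else if (is.character(subset) && length(subset) == 1) {
    sets <- build_condition_sets(epochs)
    if (!subset %in% names(sets)) {
      stop(sprintf("unknown partition '%s'", subset), call. = FALSE)
    }
    mask <- sets[[subset]]
    partition <- subset
  } else if (is.logical(subset)) {
    mask <- subset & epochs$info$kept
  } else {
    mask <- rep(FALSE, dim(epochs$data)[3])
    mask[subset] <- TRUE
    mask <- mask & epochs$info$kept
  }
  idx <- which(mask)
  if (length(idx) == 0) {
    stop(sprintf("no epochs to average in partition '%s'", partition),
         call. = FALSE)
  }
  avg <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  structure(
    list(
      data = `colnames<-`(avg, epochs$channels),
      times_ms = epochs$times_ms,
      srate = epochs$srate,
      channels = epochs$channels,
      n_epochs = length(idx),
      partition = partition
    ),
    class = "eeg_erp"
  )
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %s average of %d epochs, %d channels @ %g Hz\n",
              x$partition, x$n_epochs, length(x$channels), x$srate))
  invisible(x)
}

#' @export
as_tibble.eeg_erp <- function(x, ...) {
  tibble::tibble(
    time_ms = rep(x$times_ms, times = length(x$channels)),
    channel = rep(x$channels, each = length(x$times_ms)),
    amplitude = as.vector(x$data)
  )
}

#' P600 features of an ERP waveform
#'
#' For each analysis electrode, the amplitude is the mean over the samples
#' whose time lies in the (closed) P600 window, and the latency is the time
#' of the maximum sample in that window, earliest sample winning ties.
#'
#' @param erp An `eeg_erp` (or an `eeg_epochs` single-epoch slice).
#' @param spec An [epoch_spec()] providing the window and electrode set.
#' @return Tibble with columns `electrode`, `amplitude` (uV), `latency` (ms
#'   post-stimulus), `n_epochs`.
#' @export
p600_features <- function(erp, spec = epoch_spec()) {
  stopifnot(inherits(erp, "eeg_erp"))
  win <- spec$p600_window
  idx <- which(erp$times_ms >= win[1] - 1e-9 & erp$times_ms <= win[2] + 1e-9)
  if (length(idx) == 0 || min(erp$times_ms) > win[1] ||
      max(erp$times_ms) < win[2] - 1000 / erp$srate) {
    stop("ERP waveform does not cover the P600 window", call. = FALSE)
  }
  electrodes <- spec$electrodes[spec$electrodes %in% erp$channels]
  if (length(electrodes) == 0) {
    stop("none of the analysis electrodes are present in the waveform",
         call. = FALSE)
  }
  seg <- erp$data[idx, electrodes, drop = FALSE]
  tibble::tibble(
    electrode = electrodes,
    amplitude = unname(colMeans(seg)),
    latency = erp$times_ms[idx][apply(seg, 2, which.max)],
    n_epochs = erp$n_epochs
  )
}
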