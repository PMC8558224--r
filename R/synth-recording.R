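#' Synthesize a multichannel EEG recording with known ground truth
#'
#' Builds a recording as the sum of: spectrally shaped (1/f^beta) background
#' noise; one Gaussian P600-like positivity per target event; per R-peak, a
#' Hann-windowed alpha burst in each heartbeat-evoked component window plus a
#' slow positive deflection spanning both; and sporadic high-amplitude
#' artifact transients. Component scalp maps are zero-mean across channels
#' (average-reference convention): the analysis electrodes carry the named
#' weights and the remaining channels share a compensating negative weight.
#'
#' Heartbeat interference: a target whose epoch contains an R-peak in the
#' overlap window (derived from `model$hep1_window` and `model$p600_window`,
#' see [derive_overlap_window()]) has its evoked pulse multiplied by
#' `max(0, 1 - hep_gain * (1 - hep_erp_attenuation))` — sessions with stronger
#' cardiac coupling mask beat-coincident responses more deeply — and receives
#' a stimulus-locked alpha ripple across the P600 window
#' (`hep_coherent_alpha`). The per-target amplitude actually injected is
#' recorded in the ground truth.
#'
#' @param events Tibble of stimulus events (needs `onset_s`, `is_target`), as
#'   from [generate_paradigm_events()].
#' @param rpeaks Tibble with `time_s` (or a bare numeric vector of beat times).
#' @param model A [component_model()]. `p600_amplitude` / `p600_latency` may
#'   be scalars or named per-electrode vectors.
#' @param acquisition An [acquisition_config()]; the recording is generated at
#'   `acquisition$native_rate`.
#' @param seed Integer seed.
#' @param duration_s Recording length in seconds; defaults to 1 s past the
#'   last event or beat.
#' @return An object of class `eeg_recording`: a list with `signals` (samples
#'   x channels matrix, uV), `srate`, `channels`, `events`, `rpeaks` and a
#'   ground-truth list `truth`.
#' @export
synthesize_recording <- function(events,
                                 rpeaks,
                                 model = component_model(),
                                 acquisition = acquisition_config(),
                                 seed = 1,
                                 duration_s = NULL) {
  stopifnot(inherits(model, "component_model"),
            inherits(acquisition, "acquisition_config"))
  fs <- acquisition$native_rate
  if (fs <= 2 * model$hep_alpha_freq) {
    stop("native_rate too low for hep_alpha_freq (Nyquist violated)",
         call. = FALSE)
  }
  rpeak_times <- if (is.data.frame(rpeaks)) rpeaks$time_s else as.numeric(rpeaks)
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble::tibble(onset_s = numeric(), is_target = logical())
  }
  if (is.null(duration_s)) {
    duration_s <- max(c(events$onset_s, rpeak_times, 0)) + 1
  }
  if ((nrow(events) > 0 && max(events$onset_s) > duration_s) ||
      (length(rpeak_times) > 0 && max(rpeak_times) > duration_s)) {
    stop("events/R-peaks extend past the recording duration", call. = FALSE)
  }
  n <- round(duration_s * fs)
  chans <- acquisition$channel_labels
  n_ch <- length(chans)

  electrodes <- names(model$electrode_topography)
  amp_e <- per_electrode(model$p600_amplitude, model$electrode_topography)
  lat_e <- per_electrode(model$p600_latency,
                         stats::setNames(rep(1, length(electrodes)), electrodes))
  hep_topo <- expand_topography(model$hep_topography, chans)
  overlap <- derive_overlap_window(model$hep1_window, model$p600_window)
  sigma_s <- model$p600_width / (2 * sqrt(2 * log(2))) / 1000

  tgt <- events[events$is_target, , drop = FALSE]
  # interference depth scales with the cardiac-coupling gain: sessions with
  # stronger heartbeat coupling suppress the evoked response of beat-affected
  # epochs more
  atten_eff <- max(0, 1 - model$hep_gain * (1 - model$hep_erp_attenuation))
  lat_shift_s <- model$hep_latency_shift * model$hep_gain / 1000

  withr::with_seed(seed, {
    x <- if (model$noise_rms > 0 && n > 0) {
      shaped_noise(n, n_ch, model$noise_spectrum_exponent, model$noise_rms)
    } else {
      matrix(0, n, n_ch)
    }

    attenuated <- logical(nrow(tgt))
    if (nrow(tgt) > 0) {
      lat_groups <- split(electrodes, round(lat_e, 6))
      rest <- setdiff(chans, electrodes)
      mean_lat <- mean(lat_e)
      for (i in seq_len(nrow(tgt))) {
        onset <- tgt$onset_s[i]
        beat_lat <- (rpeak_times - onset) * 1000
        attenuated[i] <- any(beat_lat >= overlap$lower &
                               beat_lat <= overlap$upper)
        gain <- if (attenuated[i]) atten_eff else 1
        shift <- if (attenuated[i]) lat_shift_s else 0
        if (attenuated[i] && model$hep_coherent_alpha != 0 &&
            model$hep_gain != 0) {
          cb <- burst_contrib(n, fs, onset, model$p600_window,
                              model$hep_alpha_freq)
          if (!is.null(cb)) {
            x[cb$i0:cb$i1, ] <- x[cb$i0:cb$i1, ] +
              outer(cb$wave * model$hep_coherent_alpha * model$hep_gain,
                    as.numeric(hep_topo))
          }
        }
        if (gain != 0) {
          for (grp in lat_groups) {
            w <- stats::setNames(numeric(n_ch), chans)
            w[grp[grp %in% chans]] <- amp_e[grp[grp %in% chans]] * gain
            cb <- gaussian_contrib(n, fs, onset + lat_e[grp[1]] / 1000 + shift,
                                   sigma_s)
            if (!is.null(cb)) {
              x[cb$i0:cb$i1, ] <- x[cb$i0:cb$i1, ] +
                outer(cb$wave, as.numeric(w))
            }
          }
          if (length(rest) > 0) {
            w <- stats::setNames(numeric(n_ch), chans)
            w[rest] <- -sum(amp_e) * gain / length(rest)
            cb <- gaussian_contrib(n, fs, onset + mean_lat / 1000 + shift,
                                   sigma_s)
            if (!is.null(cb)) {
              x[cb$i0:cb$i1, ] <- x[cb$i0:cb$i1, ] +
                outer(cb$wave, as.numeric(w))
            }
          }
        }
      }
    }

    if (length(rpeak_times) > 0 && model$hep_gain != 0) {
      g <- model$hep_gain
      f <- model$hep_alpha_freq
      hep_w <- as.numeric(hep_topo)
      specs <- list(
        list(win = model$hep1_window, amp = g * model$hep_amplitude, f = f),
        list(win = model$hep2_window,
             amp = g * model$hep_amplitude * model$hep2_relative_amplitude,
             f = f),
        list(win = c(model$hep1_window[1], model$hep2_window[2]),
             amp = g * model$hep_slow_amplitude, f = 0)
      )
      for (tb in rpeak_times) {
        for (sp in specs) {
          cb <- burst_contrib(n, fs, tb, sp$win, sp$f)
          if (!is.null(cb)) {
            x[cb$i0:cb$i1, ] <- x[cb$i0:cb$i1, ] +
              outer(cb$wave * sp$amp, hep_w)
          }
        }
      }
    }

    artifact_times <- numeric(0)
    if (model$artifact_rate > 0 && duration_s > 0.6) {
      n_art <- stats::rpois(1, model$artifact_rate / 60 * duration_s)
      if (n_art > 0) {
        artifact_times <- sort(stats::runif(n_art, 0.3, duration_s - 0.3))
        art_topo <- artifact_topography(chans)
        art_w <- as.numeric(art_topo)
        for (ta in artifact_times) {
          a <- model$artifact_amplitude * stats::runif(1, 1.05, 1.5) *
            sample(c(-1, 1), 1)
          cb <- burst_contrib(n, fs, ta, c(-120, 120), 0)
          if (!is.null(cb)) {
            x[cb$i0:cb$i1, ] <- x[cb$i0:cb$i1, ] + outer(cb$wave * a, art_w)
          }
        }
      }
    }

    structure(
      list(
        signals = `colnames<-`(x, chans),
        srate = fs,
        channels = chans,
        events = events,
        rpeaks = rpeak_times,
        truth = list(
          targets = tibble::tibble(
            onset_s = tgt$onset_s,
            amplitude = if (nrow(tgt)) {
              mean(amp_e) * ifelse(attenuated, atten_eff, 1)
            } else numeric(),
            latency_ms = rep(mean(lat_e), nrow(tgt)),
            attenuated = attenuated
          ),
          artifact_times = artifact_times,
          overlap_window = overlap,
          seed = seed
        )
      ),
      class = "eeg_recording"
    )
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d stimulus events (%d targets), %d R-peaks\n",
    ncol(x$signals), nrow(x$signals), x$srate, nrow(x$signals) / x$srate,
    nrow(x$events), sum(x$events$is_target), length(x$rpeaks)
  ))
  invisible(x)
}

# --- internal forward-model helpers -----------------------------------------

# Named per-electrode values from a scalar (scaled by weights) or named vector.
per_electrode <- function(value, weights) {
  electrodes <- names(weights)
  if (length(value) == 1 && is.null(names(value))) {
    return(stats::setNames(as.numeric(value) * as.numeric(weights), electrodes))
  }
  v <- stats::setNames(numeric(length(electrodes)), electrodes)
  common <- intersect(names(value), electrodes)
  v[common] <- value[common]
  v
}

# Zero-mean expansion of a named topography onto the full channel set.
expand_topography <- function(weights, channels) {
  w <- stats::setNames(rep(0, length(channels)), channels)
  named <- intersect(names(weights), channels)
  w[named] <- weights[named]
  rest <- setdiff(channels, named)
  if (length(rest) > 0 && length(named) > 0) {
    w[rest] <- -sum(weights[named]) / length(rest)
  }
  w
}

artifact_topography <- function(channels) {
  frontal <- grepl("^(Fp|AF|F)", channels)
  if (!any(frontal)) frontal[1] <- TRUE
  ifelse(frontal, 1, 0.15)
}

# 1/f^beta Gaussian noise, column-wise, normalized to the requested RMS.
# FFT length is padded to the next 2-3-5-smooth integer for speed.
shaped_noise <- function(n, n_ch, beta, rms) {
  nf <- stats::nextn(n, c(2, 3, 5))
  if (beta != 0 && nf > 2) {
    # complex Gaussian spectrum shaped by k^(-beta/2); the real part of the
    # inverse transform is Gaussian noise with the target spectrum
    k <- c(0, seq_len(nf - 1))
    k <- pmin(k, nf - k)
    gain <- ifelse(k == 0, 0, k^(-beta / 2))
    spec <- matrix(complex(real = stats::rnorm(nf * n_ch),
                           imaginary = stats::rnorm(nf * n_ch)),
                   nf, n_ch) * gain
    w <- Re(stats::mvfft(spec, inverse = TRUE)) / sqrt(nf)
  } else {
    w <- matrix(stats::rnorm(nf * n_ch), nf, n_ch)
  }
  w <- w[seq_len(n), , drop = FALSE]
  sds <- apply(w, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(w, 2, rms / sds, `*`)
}

# Gaussian pulse peaking at mu_s with SD sigma_s: sample indices + waveform.
gaussian_contrib <- function(n, fs, mu_s, sigma_s) {
  i0 <- max(1L, floor((mu_s - 4 * sigma_s) * fs) + 1L)
  i1 <- min(n, ceiling((mu_s + 4 * sigma_s) * fs) + 1L)
  if (i1 < i0) return(NULL)
  tt <- (seq(i0, i1) - 1) / fs
  list(i0 = i0, i1 = i1, wave = exp(-0.5 * ((tt - mu_s) / sigma_s)^2))
}

# Hann-windowed burst over window_ms relative to anchor_s: sinusoidal carrier
# for freq > 0, a smooth unimodal lobe for freq == 0.
burst_contrib <- function(n, fs, anchor_s, window_ms, freq) {
  t0 <- anchor_s + window_ms[1] / 1000
  t1 <- anchor_s + window_ms[2] / 1000
  i0 <- max(1L, floor(t0 * fs) + 2L)
  i1 <- min(n, ceiling(t1 * fs))
  if (i1 <= i0) return(NULL)
  tt <- (seq(i0, i1) - 1) / fs
  phase <- (tt - t0) / (t1 - t0)
  env <- 0.5 - 0.5 * cos(2 * pi * phase)
  wave <- if (freq > 0) env * sin(2 * pi * freq * (tt - t0)) else env
  list(i0 = i0, i1 = i1, wave = wave)
}
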