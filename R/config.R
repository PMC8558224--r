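#' Paradigm configuration for the rapid serial visual presentation (RSVP) task
#'
#' Describes the timing of the target-detection task: alphanumeric characters
#' streamed at `stimulus_rate`, a small fraction of which are targets, arranged
#' in trials, blocks and sequences. Targets are kept at least
#' `min_intertarget_interval` seconds apart so that consecutive target-locked
#' epochs never overlap.
#'
#' @param stimulus_rate Presentation rate in Hz (default 6).
#' @param n_characters Size of the alphanumeric set shown (default 12).
#' @param target_probability Per-stimulus probability of a target (default
#'   0.05). The generator compensates for the refractory gap after each target
#'   so the realized long-run target fraction stays close to this value.
#' @param min_intertarget_interval Minimum spacing between consecutive target
#'   onsets, in seconds (default 1).
#' @param sequences_per_trial Number of character sequences per trial (5).
#' @param trial_duration Trial length in seconds (10).
#' @param intertrial_interval Gap between trials in seconds (2).
#' @param trials_per_block Trials per block (5).
#' @param n_blocks Number of blocks when `total_targets` is `NULL` (15).
#' @param total_targets If not `NULL`, the session is extended block by block
#'   until exactly this many targets have been presented (default 375).
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(stimulus_rate = 6,
                            n_characters = 12,
                            target_probability = 0.05,
                            min_intertarget_interval = 1,
                            sequences_per_trial = 5,
                            trial_duration = 10,
                            intertrial_interval = 2,
                            trials_per_block = 5,
                            n_blocks = 15,
                            total_targets = 375) {
  if (stimulus_rate <= 0 || trial_duration <= 0) {
    stop("stimulus_rate and trial_duration must be strictly positive",
         call. = FALSE)
  }
  if (intertrial_interval < 0 || min_intertarget_interval < 0) {
    stop("intervals must be non-negative", call. = FALSE)
  }
  if (target_probability <= 0 || target_probability >= 1) {
    stop("target_probability must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_blocks < 0 || trials_per_block <= 0) {
    stop("n_blocks must be >= 0 and trials_per_block >= 1", call. = FALSE)
  }
  if (!is.null(total_targets) && (is.na(total_targets) || total_targets < 0)) {
    stop("total_targets must be NULL or a non-negative count", call. = FALSE)
  }
  structure(
    list(
      stimulus_rate = stimulus_rate,
      n_characters = n_characters,
      target_probability = target_probability,
      min_intertarget_interval = min_intertarget_interval,
      sequences_per_trial = sequences_per_trial,
      trial_duration = trial_duration,
      intertrial_interval = intertrial_interval,
      trials_per_block = trials_per_block,
      n_blocks = n_blocks,
      total_targets = total_targets
    ),
    class = "paradigm_config"
  )
}

#' Cardiac rhythm configuration
#'
#' RR intervals are drawn from a normal distribution truncated at
#' `mean_rr` +/- `truncate_sd` standard deviations, which keeps every interval
#' strictly positive and matches a reported mean +/- SD summary.
#'
#' @param mean_rr Mean RR interval in seconds (default 0.81, about 74 bpm).
#' @param sd_rr Standard deviation of the RR interval in seconds (default
#'   0.05). `sd_rr = 0` gives a perfectly regular train.
#' @param truncate_sd Truncation point in SD units (default 3).
#' @return A list of class `cardiac_config`.
#' @export
cardiac_config <- function(mean_rr = 0.81, sd_rr = 0.05, truncate_sd = 3) {
  if (mean_rr <= 0) stop("mean_rr must be positive", call. = FALSE)
  if (sd_rr < 0) stop("sd_rr must be non-negative", call. = FALSE)
  if (mean_rr <= truncate_sd * sd_rr) {
    stop("mean_rr must exceed truncate_sd * sd_rr (RR intervals must stay positive)",
         call. = FALSE)
  }
  structure(
    list(mean_rr = mean_rr, sd_rr = sd_rr, truncate_sd = truncate_sd),
    class = "cardiac_config"
  )
}

#' Forward model for the synthetic EEG components
#'
#' Ground-truth description of what the generator injects on top of spectrally
#' shaped background noise: a P600-like positivity per target, two
#' R-peak-locked heartbeat-evoked components (an alpha burst plus a slow
#' deflection), occasional high-amplitude artifact transients, and an
#' interference rule by which the evoked response of epochs whose R-peak falls
#' in the heartbeat-overlap window is attenuated.
#'
#' @param p600_amplitude Peak amplitude of the P600 pulse in microvolts. Either
#'   a scalar (scaled by the topography) or a named vector giving the peak
#'   amplitude per analysis electrode directly.
#' @param p600_latency Peak latency in ms post-stimulus; scalar or named
#'   per-electrode vector.
#' @param p600_width Full width at half maximum of the Gaussian pulse, ms.
#' @param p600_window Search window for the component, ms post-stimulus; with
#'   `hep1_window` it determines which R-peak latencies interfere.
#' @param hep1_window First heartbeat-evoked component, ms post-R (50-250).
#' @param hep2_window Second heartbeat-evoked component, ms post-R (250-600).
#' @param hep_alpha_freq Frequency of the HEP alpha burst, Hz (10).
#' @param hep_amplitude Peak amplitude of the first-component alpha burst, uV.
#' @param hep2_relative_amplitude Second-component amplitude relative to the
#'   first.
#' @param hep_slow_amplitude Amplitude of the slow HEP deflection spanning both
#'   components, uV.
#' @param hep_gain Multiplicative cardiac-coupling gain on all HEP components;
#'   cohort simulations draw this per session.
#' @param hep_erp_attenuation Baseline multiplier applied to the evoked P600
#'   of a target whose epoch contains an R-peak inside the heartbeat-overlap
#'   window (derived from `hep1_window` and `p600_window`). The effective
#'   multiplier deepens with the session's cardiac coupling:
#'   `max(0, 1 - hep_gain * (1 - hep_erp_attenuation))`; 1 disables
#'   interference.
#' @param hep_latency_shift Delay, in ms per unit coupling gain, added to the
#'   evoked response of beat-coincident epochs (cardiac phase resetting of
#'   the surviving response). 0 disables the shift.
#' @param hep_coherent_alpha Amplitude, uV per unit coupling gain, of the
#'   alpha wave added to beat-coincident epochs across the P600 window,
#'   phase-locked to the stimulus. R-peaks inside the overlap window occur at
#'   similar latencies, so their evoked alpha survives averaging as a
#'   quasi-coherent ripple; this term models that residual directly.
#' @param electrode_topography Named weights per channel for the P600. Channels
#'   absent from the vector receive a compensating negative weight so the
#'   topography is zero-mean, as average-referenced scalp maps are.
#' @param hep_topography Same, for the HEP components.
#' @param noise_spectrum_exponent Spectral exponent beta of the 1/f^beta
#'   background noise (default 1).
#' @param noise_rms RMS of the background noise per channel, uV.
#' @param artifact_rate Rate of artifact transients, events per minute
#'   (residual rate after upstream cleanup; each transient is a 240 ms lobe).
#' @param artifact_amplitude Peak amplitude of artifact transients, uV (>100 so
#'   that threshold rejection catches them).
#' @return A list of class `component_model`.
#' @export
component_model <- function(p600_amplitude = 5,
                            p600_latency = 620,
                            p600_width = 160,
                            p600_window = c(530, 750),
                            hep1_window = c(50, 250),
                            hep2_window = c(250, 600),
                            hep_alpha_freq = 10,
                            hep_amplitude = 5,
                            hep2_relative_amplitude = 0.15,
                            hep_slow_amplitude = 0.5,
                            hep_gain = 1,
                            hep_erp_attenuation = 0,
                            hep_latency_shift = 0,
                            hep_coherent_alpha = 3,
                            electrode_topography = NULL,
                            hep_topography = NULL,
                            noise_spectrum_exponent = 1,
                            noise_rms = 2.5,
                            artifact_rate = 0.5,
                            artifact_amplitude = 150) {
  stopifnot(length(hep1_window) == 2, length(hep2_window) == 2,
            length(p600_window) == 2)
  if (hep1_window[1] >= hep1_window[2] || hep2_window[1] >= hep2_window[2] ||
      p600_window[1] >= p600_window[2]) {
    stop("component windows must be ordered (start < end)", call. = FALSE)
  }
  if (!isTRUE(all.equal(hep1_window[2], hep2_window[1]))) {
    stop("hep1_window must end where hep2_window starts", call. = FALSE)
  }
  if (!all(is.finite(c(p600_amplitude, hep_amplitude, hep_slow_amplitude)))) {
    stop("component amplitudes must be finite", call. = FALSE)
  }
  if (p600_width <= 0) stop("p600_width must be positive", call. = FALSE)
  if (hep_erp_attenuation < 0) {
    stop("hep_erp_attenuation must be non-negative", call. = FALSE)
  }
  if (hep_latency_shift < 0) {
    stop("hep_latency_shift must be non-negative", call. = FALSE)
  }
  if (is.null(electrode_topography)) {
    electrode_topography <- c(
      F3 = 0.7, F4 = 0.7, C3 = 0.9, C4 = 0.9,
      P3 = 1.0, P4 = 1.0, O1 = 0.8, O2 = 0.8
    )
  }
  if (is.null(hep_topography)) {
    hep_topography <- c(
      F3 = 1.0, F4 = 1.0, C3 = 0.8, C4 = 0.8,
      P3 = 0.6, P4 = 0.6, O1 = 0.4, O2 = 0.4
    )
  }
  structure(
    list(
      p600_amplitude = p600_amplitude,
      p600_latency = p600_latency,
      p600_width = p600_width,
      p600_window = p600_window,
      hep1_window = hep1_window,
      hep2_window = hep2_window,
      hep_alpha_freq = hep_alpha_freq,
      hep_amplitude = hep_amplitude,
      hep2_relative_amplitude = hep2_relative_amplitude,
      hep_slow_amplitude = hep_slow_amplitude,
      hep_gain = hep_gain,
      hep_erp_attenuation = hep_erp_attenuation,
      hep_latency_shift = hep_latency_shift,
      hep_coherent_alpha = hep_coherent_alpha,
      electrode_topography = electrode_topography,
      hep_topography = hep_topography,
      noise_spectrum_exponent = noise_spectrum_exponent,
      noise_rms = noise_rms,
      artifact_rate = artifact_rate,
      artifact_amplitude = artifact_amplitude
    ),
    class = "component_model"
  )
}

#' EEG acquisition configuration
#'
#' @param native_rate Acquisition sampling rate in Hz (default 2048).
#' @param analysis_rate Rate the recording is down-sampled to before epoching
#'   (default 512). Must be achievable from `native_rate` by rational
#'   resampling; the default is an exact integer decimation.
#' @param n_channels Number of EEG channels (default 64).
#' @param channel_labels Channel names in the 10-20/10-10 system; defaults to a
#'   standard 64-channel montage (truncated or extended for other
#'   `n_channels`, always containing the eight analysis electrodes).
#' @param reject_threshold Absolute amplitude threshold for epoch rejection,
#'   uV (default 100).
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(native_rate = 2048,
                               analysis_rate = 512,
                               n_channels = 64,
                               channel_labels = NULL,
                               reject_threshold = 100) {
  if (native_rate <= 0 || analysis_rate <= 0) {
    stop("sampling rates must be positive", call. = FALSE)
  }
  if (analysis_rate > native_rate) {
    stop("analysis_rate cannot exceed native_rate", call. = FALSE)
  }
  if (reject_threshold <= 0) {
    stop("reject_threshold must be positive", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- default_montage(n_channels)
  }
  if (length(channel_labels) != n_channels) {
    stop("channel_labels must have length n_channels", call. = FALSE)
  }
  structure(
    list(
      native_rate = native_rate,
      analysis_rate = analysis_rate,
      n_channels = n_channels,
      channel_labels = channel_labels,
      reject_threshold = reject_threshold
    ),
    class = "acquisition_config"
  )
}

#' Standard 64-channel montage labels
#'
#' The usual 64-electrode 10-10 layout. For fewer channels the eight analysis
#' electrodes (F3, F4, C3, C4, P3, P4, O1, O2) come first, padded with midline
#' and temporal sites; for more than 64, generic labels are appended.
#'
#' @param n Number of channels.
#' @return Character vector of length `n`.
#' @export
default_montage <- function(n = 64) {
  full64 <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7",
    "FC5", "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7",
    "CP5", "CP3", "CP1", "P1", "P3", "P5", "P7", "P9",
    "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
    "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz",
    "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4", "CP2",
    "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  if (n == 64) return(full64)
  core <- c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
            "Fz", "Cz", "Pz", "Oz", "F7", "F8", "T7", "T8",
            "Fp1", "Fp2", "P7", "P8", "FC1", "FC2", "CP1", "CP2")
  if (n <= length(core)) return(core[seq_len(n)])
  c(core, sprintf("EEG%03d", seq_len(n - length(core))))
}

#' Epoching and P600 feature specification
#'
#' Epochs span `[-pre_ms, post_ms)` around each target onset (half-open so the
#' sample count is exact), the pre-stimulus segment defines the baseline, and
#' P600 features are computed inside `p600_window` (endpoints inclusive) on the
#' eight analysis electrodes.
#'
#' @param pre_ms Pre-stimulus span, ms (200).
#' @param post_ms Post-stimulus span, ms (800).
#' @param p600_window Feature window, ms post-stimulus (530-750).
#' @param electrodes Analysis electrodes.
#' @return A list of class `epoch_spec`.
#' @export
epoch_spec <- function(pre_ms = 200,
                       post_ms = 800,
                       p600_window = c(530, 750),
                       electrodes = c("F3", "F4", "C3", "C4",
                                      "P3", "P4", "O1", "O2")) {
  if (pre_ms < 0 || post_ms <= 0) {
    stop("pre_ms must be >= 0 and post_ms > 0", call. = FALSE)
  }
  if (length(p600_window) != 2 || p600_window[1] >= p600_window[2]) {
    stop("p600_window must be an ordered pair", call. = FALSE)
  }
  if (p600_window[1] <= 0 || p600_window[2] > post_ms) {
    stop("p600_window must lie inside (0, post_ms]", call. = FALSE)
  }
  structure(
    list(pre_ms = pre_ms, post_ms = post_ms,
         p600_window = p600_window, electrodes = electrodes),
    class = "epoch_spec"
  )
}

#' Between-condition effect configuration for cohort simulation
#'
#' Controls how the post-task session differs from the pre-task session in
#' each workload condition. Effects are parameterized as standardized mean
#' differences (Hedges' g) of the post-minus-pre feature change between the
#' high and low workload conditions; the implied shift in physical units is
#' `g * sqrt(between_sd^2 + site_sd^2)`, the per-electrode population SD.
#' Subject-level variability has a global component (`*_between_sd`, shared by
#' all electrodes) and a site component (`*_site_sd`, drawn independently per
#' electrode), so electrodes are informative but not perfectly redundant.
#'
#' @param amplitude_g Standardized high-minus-low effect on the P600 amplitude
#'   change (negative: high workload reduces the amplitude).
#' @param amplitude_between_sd,amplitude_site_sd Between-subject SDs of the
#'   amplitude change, uV.
#' @param latency_g Standardized effect on the P600 latency change (positive:
#'   high workload prolongs the latency).
#' @param latency_between_sd,latency_site_sd Between-subject SDs of the
#'   latency change, ms.
#' @param coupling_cv Coefficient of variation of the lognormal per-session
#'   cardiac-coupling gain multiplying the HEP components.
#' @param rr_shift_high Change of the mean RR interval in the high workload
#'   condition, seconds (default -0.02: 0.81 -> 0.79).
#' @param smeq_low,smeq_high Mean and SD of the post-task subjective
#'   mental-effort (SMEQ) score per condition, on the 0-150 scale.
#' @param smeq_pre Mean and SD of the pre-task SMEQ score.
#' @param baseline_amplitude Mean and between-subject SD of the pre-task P600
#'   peak amplitude, uV.
#' @param baseline_latency Mean and between-subject SD of the pre-task P600
#'   peak latency, ms.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(amplitude_g = -1.5,
                          amplitude_between_sd = 1,
                          amplitude_site_sd = 4.35,
                          latency_g = 1.7,
                          latency_between_sd = 8,
                          latency_site_sd = 20,
                          coupling_cv = 0.5,
                          rr_shift_high = -0.02,
                          smeq_low = c(mean = 13.79, sd = 6.37),
                          smeq_high = c(mean = 71.64, sd = 20.59),
                          smeq_pre = c(mean = 12, sd = 5),
                          baseline_amplitude = c(mean = 12, sd = 1),
                          baseline_latency = c(mean = 620, sd = 10)) {
  structure(
    list(
      amplitude_g = amplitude_g,
      amplitude_between_sd = amplitude_between_sd,
      amplitude_site_sd = amplitude_site_sd,
      latency_g = latency_g,
      latency_between_sd = latency_between_sd,
      latency_site_sd = latency_site_sd,
      coupling_cv = coupling_cv,
      rr_shift_high = rr_shift_high,
      smeq_low = smeq_low,
      smeq_high = smeq_high,
      smeq_pre = smeq_pre,
      baseline_amplitude = baseline_amplitude,
      baseline_latency = baseline_latency
    ),
    class = "effect_config"
  )
}

#' RBF-SVM classifier specification
#'
#' @param kernel_scale Length-scale s of the RBF kernel
#'   `k(a, b) = exp(-||a - b||^2 / (2 s^2))`, either a scalar or a named vector
#'   with one scale per partition condition. Defaults to the per-condition
#'   scales reported for real recordings (ERP_T 117.8, ERP_HEP 2.7,
#'   ERP_A-HEP 21.5).
#' @param cost Soft-margin box constraint C (default 1).
#' @param folds Number of cross-validation folds (default 10, stratified).
#' @param positive_class Label treated as the positive class (default "high").
#' @param seed Seed for the fold assignment.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kernel_scale = c(ERP_T = 117.8,
                                             ERP_HEP = 2.7,
                                             `ERP_A-HEP` = 21.5),
                            cost = 1,
                            folds = 10,
                            positive_class = "high",
                            seed = 1) {
  if (any(kernel_scale <= 0)) stop("kernel_scale must be positive", call. = FALSE)
  if (folds < 2) stop("folds must be at least 2", call. = FALSE)
  if (cost <= 0) stop("cost must be positive", call. = FALSE)
  structure(
    list(kernel_scale = kernel_scale, cost = cost, folds = folds,
         positive_class = positive_class, seed = seed),
    class = "classifier_spec"
  )
}
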