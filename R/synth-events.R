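#' Generate the stimulus event stream for an RSVP session
#'
#' Stimulus onsets fall on a strict `1/stimulus_rate` grid inside each trial.
#' Each onset is a target with probability `target_probability`, subject to a
#' refractory rule: a stimulus is only eligible to be a target if at least
#' `min_intertarget_interval` seconds have elapsed since the previous target.
#' The Bernoulli probability at eligible positions is inflated to
#' `p / (1 - k p)` (k = number of grid positions blocked after a target) so the
#' realized long-run target fraction stays close to `target_probability`.
#'
#' When `config$total_targets` is set, blocks are appended beyond
#' `config$n_blocks` until that many targets have occurred, and the stream
#' stops at the end of the trial containing the last target. With
#' `total_targets = NULL` the session is exactly `n_blocks` blocks.
#'
#' @param config A [paradigm_config()].
#' @param seed Integer seed; the stream is deterministic given the seed.
#' @return A tibble with columns `onset_s`, `is_target`, `block`, `trial`
#'   (trial index within the session) and `stimulus` (the character shown).
#' @export
generate_paradigm_events <- function(config = paradigm_config(), seed = 1) {
  stopifnot(inherits(config, "paradigm_config"))
  if (config$n_blocks == 0) {
    return(tibble::tibble(onset_s = numeric(), is_target = logical(),
                          block = integer(), trial = integer(),
                          stimulus = character()))
  }
  rate <- config$stimulus_rate
  p <- config$target_probability
  n_stim_trial <- round(config$trial_duration * rate)
  gap_slots <- ceiling(config$min_intertarget_interval * rate - 1e-9)
  k_blocked <- max(gap_slots - 1, 0)
  p_adj <- min(p / max(1 - k_blocked * p, .Machine$double.eps), 0.999)
  fixed_session <- is.null(config$total_targets)
  n_trials_min <- config$n_blocks * config$trials_per_block
  trial_span <- config$trial_duration + config$intertrial_interval

  nontargets <- LETTERS[seq_len(max(config$n_characters - 1, 1))]

  withr::with_seed(seed, {
    onsets <- list()
    targets <- list()
    n_targets <- 0L
    trial <- 0L
    last_target_onset <- -Inf
    repeat {
      if (fixed_session && trial >= n_trials_min) break
      if (!fixed_session && n_targets >= config$total_targets &&
          trial >= 1L) break
      if (!fixed_session && trial >= n_trials_min &&
          config$total_targets == 0) break
      trial_start <- trial * trial_span
      t_on <- trial_start + (seq_len(n_stim_trial) - 1L) / rate
      draws <- stats::runif(n_stim_trial)
      is_t <- logical(n_stim_trial)
      for (j in seq_len(n_stim_trial)) {
        if (!fixed_session && n_targets >= config$total_targets) break
        eligible <- (t_on[j] - last_target_onset) >=
          config$min_intertarget_interval - 1e-9
        if (eligible && draws[j] < p_adj) {
          is_t[j] <- TRUE
          last_target_onset <- t_on[j]
          n_targets <- n_targets + 1L
        }
      }
      trial <- trial + 1L
      onsets[[trial]] <- t_on
      targets[[trial]] <- is_t
      if (fixed_session && trial >= n_trials_min) break
      if (!fixed_session && n_targets >= config$total_targets) break
      if (!fixed_session && trial >= 50L * max(n_trials_min, 1L)) {
        stop("could not reach total_targets; target_probability too low?",
             call. = FALSE)
      }
    }
    onset_s <- unlist(onsets)
    is_target <- unlist(targets)
    n <- length(onset_s)
    stim <- sample(nontargets, n, replace = TRUE)
    stim[is_target] <- "5"
    trial_idx <- rep(seq_len(trial), each = n_stim_trial)[seq_len(n)]
    tibble::tibble(
      onset_s = onset_s,
      is_target = is_target,
      block = (trial_idx - 1L) %/% config$trials_per_block + 1L,
      trial = trial_idx,
      stimulus = stim
    )
  })
}

#' Generate an R-peak event train
#'
#' Inter-beat intervals are drawn from the truncated normal distribution
#' described by a [cardiac_config()]. The first beat is placed at time 0, so a
#' zero-variance configuration is fully deterministic.
#'
#' @param duration Length of the train in seconds (> 0).
#' @param cardiac A [cardiac_config()].
#' @param seed Integer seed.
#' @return A tibble with a single column `time_s` of strictly increasing beat
#'   times in `[0, duration]`.
#' @export
generate_rpeaks <- function(duration, cardiac = cardiac_config(), seed = 1) {
  stopifnot(inherits(cardiac, "cardiac_config"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  m <- cardiac$mean_rr
  s <- cardiac$sd_rr
  n_guess <- ceiling(duration / m * 1.25) + 10L
  withr::with_seed(seed, {
    times <- 0
    repeat {
      rr <- rtruncnorm(n_guess, m, s, cardiac$truncate_sd)
      new_times <- times[length(times)] + cumsum(rr)
      times <- c(times, new_times)
      if (times[length(times)] > duration) break
    }
  })
  tibble::tibble(time_s = times[times <= duration + 1e-9])
}

# Truncated-normal draws via inverse-CDF so a given seed uses exactly n
# uniforms regardless of the truncation bounds.
rtruncnorm <- function(n, mean, sd, truncate_sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(-truncate_sd)
  hi <- stats::pnorm(truncate_sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo)) * sd + mean
}
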