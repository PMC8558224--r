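#' Simulate a pre/post x low/high workload cohort
#'
#' Draws per-subject, per-session ground truth for a within-subject workload
#' study: every subject contributes four sessions (pre and post ERP task in
#' each of the low- and high-workload conditions). Post-task sessions carry a
#' condition-dependent change of the P600 (reduced amplitude, prolonged
#' latency under high workload) composed of a fixed shift plus global and
#' per-site between-subject variability (see [effect_config()]); subjective
#' mental-effort (SMEQ) scores are drawn from the condition distributions and
#' clipped to the 0-150 scale; the high-workload condition shortens the mean
#' RR interval; and each session draws a lognormal cardiac-coupling gain that
#' scales the heartbeat-evoked components.
#'
#' The returned plan is light-weight (ground truth only). Recordings are
#' generated per session by [simulate_session()] — or set
#' `keep_recordings = TRUE` to attach them as a list-column, which is only
#' advisable for small cohorts at reduced acquisition settings.
#'
#' @param n_subjects Number of subjects (>= 2; default 14).
#' @param paradigm A [paradigm_config()].
#' @param cardiac A [cardiac_config()].
#' @param model A [component_model()].
#' @param effect An [effect_config()].
#' @param acquisition An [acquisition_config()].
#' @param seed Master seed; all session-level seeds derive from it.
#' @param keep_recordings Attach a `recording` list-column (default `FALSE`).
#' @return A tibble of class `mwl_cohort`, one row per subject x condition x
#'   session, with columns `subject`, `condition` (`"low"`/`"high"`),
#'   `session` (`"pre"`/`"post"`), `smeq`, `hep_gain`, `mean_rr`, `seed`,
#'   and list-columns `amplitude` / `latency` (named per-electrode truth).
#'   The simulation configs are stored in `attr(, "configs")`.
#' @export
simulate_cohort <- function(n_subjects = 14,
                            paradigm = paradigm_config(),
                            cardiac = cardiac_config(),
                            model = component_model(),
                            effect = effect_config(),
                            acquisition = acquisition_config(),
                            seed = 1,
                            keep_recordings = FALSE) {
  if (n_subjects < 2) {
    stop("n_subjects must be at least 2 (paired statistics undefined)",
         call. = FALSE)
  }
  electrodes <- names(model$electrode_topography)

  amp_sd_tot <- sqrt(effect$amplitude_between_sd^2 +
                       effect$amplitude_site_sd^2)
  lat_sd_tot <- sqrt(effect$latency_between_sd^2 + effect$latency_site_sd^2)
  amp_shift <- c(low = 0, high = effect$amplitude_g * amp_sd_tot)
  lat_shift <- c(low = 0, high = effect$latency_g * lat_sd_tot)
  sdlog <- sqrt(log(1 + effect$coupling_cv^2))

  grid <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    condition = c("low", "high"),
    session = c("pre", "post")
  )

  rows <- withr::with_seed(seed, {
    session_seeds <- sample.int(.Machine$integer.max - 10L, nrow(grid))
    # stable subject traits: baseline P600 amplitude and latency
    a0_subj <- stats::rnorm(n_subjects, effect$baseline_amplitude[["mean"]],
                            effect$baseline_amplitude[["sd"]])
    l0_subj <- stats::rnorm(n_subjects, effect$baseline_latency[["mean"]],
                            effect$baseline_latency[["sd"]])
    purrr::pmap(
      list(grid$subject, grid$condition, grid$session, session_seeds),
      function(subj, cond, sess, sseed) {
        a0 <- a0_subj[subj]
        l0 <- l0_subj[subj]
        amp_e <- a0 * model$electrode_topography
        lat_e <- stats::setNames(rep(l0, length(electrodes)), electrodes)
        if (sess == "post") {
          da <- amp_shift[[cond]] +
            stats::rnorm(1, 0, effect$amplitude_between_sd) +
            stats::rnorm(length(electrodes), 0, effect$amplitude_site_sd)
          dl <- lat_shift[[cond]] +
            stats::rnorm(1, 0, effect$latency_between_sd) +
            stats::rnorm(length(electrodes), 0, effect$latency_site_sd)
          amp_e <- amp_e + da
          lat_e <- lat_e + dl
        }
        # keep peaks away from the window edges, where the window-mean
        # amplitude would depend strongly on latency
        win <- model$p600_window
        lat_e <- pmin(pmax(lat_e, win[1] + 30), win[2] - 50)
        smeq_par <- if (sess == "pre") effect$smeq_pre else {
          if (cond == "low") effect$smeq_low else effect$smeq_high
        }
        tibble::tibble(
          subject = subj, condition = cond, session = sess,
          smeq = min(max(stats::rnorm(1, smeq_par[["mean"]],
                                      smeq_par[["sd"]]), 0), 150),
          hep_gain = stats::rlnorm(1, -sdlog^2 / 2, sdlog),
          mean_rr = cardiac$mean_rr +
            if (cond == "high") effect$rr_shift_high else 0,
          seed = sseed,
          amplitude = list(amp_e),
          latency = list(lat_e)
        )
      }
    )
  })
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "configs") <- list(
    paradigm = paradigm, cardiac = cardiac, model = model,
    effect = effect, acquisition = acquisition, seed = seed
  )
  class(cohort) <- c("mwl_cohort", class(cohort))
  if (keep_recordings) {
    cohort$recording <- purrr::map(seq_len(nrow(cohort)),
                                   function(i) simulate_session(cohort, i))
  }
  cohort
}

#' Synthesize the recording of one cohort session
#'
#' Expands one row of a [simulate_cohort()] plan into an `eeg_recording`:
#' paradigm events and the R-peak train are generated from the session seed,
#' and the component model is specialized with the session's per-electrode
#' P600 truth and cardiac-coupling gain.
#'
#' @param cohort A [simulate_cohort()] plan.
#' @param i Row index of the session to synthesize.
#' @param paradigm,cardiac,model,acquisition Simulation configs; default to
#'   the ones stored on the cohort.
#' @return An `eeg_recording`.
#' @export
simulate_session <- function(cohort, i = 1,
                             paradigm = NULL, cardiac = NULL,
                             model = NULL, acquisition = NULL) {
  cfg <- attr(cohort, "configs")
  if (is.null(paradigm)) paradigm <- cfg$paradigm
  if (is.null(cardiac)) cardiac <- cfg$cardiac
  if (is.null(model)) model <- cfg$model
  if (is.null(acquisition)) acquisition <- cfg$acquisition
  row <- cohort[i, , drop = FALSE]
  stopifnot(nrow(row) == 1)

  events <- generate_paradigm_events(paradigm, seed = row$seed)
  duration <- max(events$onset_s) + 1.2
  rp <- generate_rpeaks(
    duration,
    cardiac_config(mean_rr = row$mean_rr, sd_rr = cardiac$sd_rr,
                   truncate_sd = cardiac$truncate_sd),
    seed = row$seed + 1L
  )
  model$p600_amplitude <- row$amplitude[[1]]
  model$p600_latency <- row$latency[[1]]
  model$hep_gain <- row$hep_gain
  synthesize_recording(events, rp, model, acquisition,
                       seed = row$seed + 2L, duration_s = duration)
}
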