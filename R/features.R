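#' Analyze one recording into partitioned P600 features
#'
#' Runs the full single-session chain: down-sample to the analysis rate,
#' common average reference, target-locked epoching, baseline correction,
#' amplitude-threshold rejection, heartbeat partitioning, per-partition
#' averaging and P600 feature extraction.
#'
#' @param recording An `eeg_recording`.
#' @param analysis_rate Analysis sampling rate in Hz; `NULL` keeps the native
#'   rate.
#' @param spec An [epoch_spec()].
#' @param window An overlap window from [derive_overlap_window()].
#' @param reject_threshold Epoch rejection threshold in uV.
#' @return Tibble with one row per partition x electrode: `partition`,
#'   `electrode`, `amplitude`, `latency`, `n_epochs`. Per-partition epoch
#'   counts are in `attr(, "counts")` and the rejection log in
#'   `attr(, "rejection_log")`.
#' @export
analyze_recording <- function(recording,
                              analysis_rate = NULL,
                              spec = epoch_spec(),
                              window = derive_overlap_window(),
                              reject_threshold = 100) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!is.null(analysis_rate) && analysis_rate != recording$srate) {
    recording <- resample_recording(recording, analysis_rate)
  }
  recording <- apply_car(recording)
  epochs <- extract_epochs(recording, spec)
  epochs <- baseline_correct(epochs)
  epochs <- reject_epochs(epochs, reject_threshold)
  epochs <- partition_epochs(epochs, window)
  sets <- build_condition_sets(epochs)

  out <- purrr::map_dfr(names(sets), function(p) {
    feats <- p600_features(average_epochs(epochs, p), spec)
    feats$partition <- p
    feats
  })
  out <- out[, c("partition", "electrode", "amplitude", "latency", "n_epochs")]
  attr(out, "counts") <- attr(sets, "counts")
  attr(out, "rejection_log") <- rejection_log(epochs)
  out
}

#' Session-level feature table for a whole cohort
#'
#' Simulates (or reuses) every session recording of a cohort plan and
#' analyzes it with [analyze_recording()], streaming session by session so
#' raw recordings are never all held in memory.
#'
#' @param cohort A [simulate_cohort()] plan.
#' @param analysis_rate,spec,window,reject_threshold Passed to
#'   [analyze_recording()]; `analysis_rate` defaults to the cohort's
#'   acquisition config.
#' @return Tidy tibble, one row per session x partition x electrode x
#'   measure: `subject`, `condition`, `session`, `partition`, `electrode`,
#'   `measure` (`"amplitude"`/`"latency"`), `value`, `smeq`, `n_epochs`.
#'   Per-session partition counts are in `attr(, "counts")`.
#' @export
cohort_features <- function(cohort,
                            analysis_rate = NULL,
                            spec = epoch_spec(),
                            window = derive_overlap_window(),
                            reject_threshold = NULL) {
  stopifnot(inherits(cohort, "mwl_cohort"))
  cfg <- attr(cohort, "configs")
  if (is.null(analysis_rate)) analysis_rate <- cfg$acquisition$analysis_rate
  if (is.null(reject_threshold)) {
    reject_threshold <- cfg$acquisition$reject_threshold
  }
  counts <- list()
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    rec <- if ("recording" %in% names(cohort)) {
      cohort$recording[[i]]
    } else {
      simulate_session(cohort, i)
    }
    feats <- analyze_recording(rec, analysis_rate = analysis_rate,
                               spec = spec, window = window,
                               reject_threshold = reject_threshold)
    cnt <- attr(feats, "counts")
    cnt$subject <- cohort$subject[i]
    cnt$condition <- cohort$condition[i]
    cnt$session <- cohort$session[i]
    counts[[i]] <<- cnt
    feats$subject <- cohort$subject[i]
    feats$condition <- cohort$condition[i]
    feats$session <- cohort$session[i]
    feats$smeq <- cohort$smeq[i]
    feats
  })
  out <- dplyr::bind_rows(rows)
  out <- tidyr::pivot_longer(out, cols = c("amplitude", "latency"),
                             names_to = "measure", values_to = "value")
  out <- out[, c("subject", "condition", "session", "partition", "electrode",
                 "measure", "value", "smeq", "n_epochs")]
  attr(out, "counts") <- dplyr::bind_rows(counts)
  out
}

#' Post-minus-pre feature changes
#'
#' Collapses the session-level feature table to one value per subject x
#' condition x partition x electrode x measure: the post-task value minus the
#' pre-task value, the quantity entering the statistics and the classifier.
#'
#' @param features Output of [cohort_features()].
#' @return Tibble with columns `subject`, `condition`, `partition`,
#'   `electrode`, `measure`, `value`.
#' @export
feature_differences <- function(features) {
  wide <- tidyr::pivot_wider(
    features,
    id_cols = c("subject", "condition", "partition", "electrode", "measure"),
    names_from = "session", values_from = "value"
  )
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("features must contain both pre and post sessions", call. = FALSE)
  }
  wide$value <- wide$post - wide$pre
  wide[, c("subject", "condition", "partition", "electrode", "measure",
           "value")]
}

#' Paired SMEQ comparison between workload conditions
#'
#' Compares the post-task subjective mental-effort scores of the two
#' conditions across subjects: paired test, group summaries, Hedges' g and
#' its 95% CI.
#'
#' @param cohort A [simulate_cohort()] plan (or any tibble with `subject`,
#'   `condition`, `session`, `smeq`).
#' @return One-row tibble with the group summaries, test and effect size.
#' @export
smeq_comparison <- function(cohort) {
  post <- cohort[cohort$session == "post", c("subject", "condition", "smeq")]
  wide <- tidyr::pivot_wider(post, names_from = "condition",
                             values_from = "smeq")
  test <- if (nrow(wide) >= 3) {
    paired_test(wide$low, wide$high)
  } else {
    tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                   method = "none (n < 3)")
  }
  g <- hedges_g(mean(wide$low), stats::sd(wide$low),
                mean(wide$high), stats::sd(wide$high),
                n1 = max(nrow(wide), 2), n2 = max(nrow(wide), 2))
  ci <- g_confidence_interval(g, max(nrow(wide), 2), max(nrow(wide), 2))
  tibble::tibble(
    n = nrow(wide),
    mean_low = mean(wide$low), sd_low = stats::sd(wide$low),
    mean_high = mean(wide$high), sd_high = stats::sd(wide$high),
    t = test$statistic, p = test$p_value, method = test$method,
    g = g, ci_lower = ci$lower, ci_upper = ci$upper
  )
}
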