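#' Export events and R-peaks as tab-separated text
#'
#' One row per event: `onset_s`, `type` (`target` / `nontarget` / `rpeak`),
#' plus optional `session` / `condition` annotations.
#'
#' @param recording An `eeg_recording`.
#' @param path Output file path.
#' @param session,condition Optional annotation strings.
#' @return Invisibly, the exported tibble.
#' @export
write_events_tsv <- function(recording, path, session = NA, condition = NA) {
  stopifnot(inherits(recording, "eeg_recording"))
  ev <- tibble::tibble(
    onset_s = c(recording$events$onset_s, recording$rpeaks),
    type = c(ifelse(recording$events$is_target, "target", "nontarget"),
             rep("rpeak", length(recording$rpeaks)))
  )
  ev <- ev[order(ev$onset_s), ]
  ev$session <- session
  ev$condition <- condition
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}

#' Read an exported event table
#'
#' @param path Path written by [write_events_tsv()].
#' @return Tibble with `onset_s`, `type`, `session`, `condition`.
#' @export
read_events_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a ground-truth sidecar as JSON
#'
#' @param recording An `eeg_recording` with a `truth` element.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_truth_json <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  truth <- recording$truth
  if (inherits(truth$overlap_window, "overlap_window")) {
    truth$overlap_window <- unclass(truth$overlap_window)
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a feature table as TSV and JSON
#'
#' @param features A feature tibble ([cohort_features()] or
#'   [feature_differences()]).
#' @param path Output path; a `.json` twin is written alongside the TSV.
#' @return Invisibly, the paths.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- sub("\\.[a-zA-Z]+$", ".json", path)
  if (json == path) json <- paste0(path, ".json")
  jsonlite::write_json(features, json, auto_unbox = TRUE, digits = NA)
  invisible(c(path, json))
}
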