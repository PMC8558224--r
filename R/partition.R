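#' Derive the heartbeat-overlap window from component timing
#'
#' An R-peak at latency r (ms after the target) interferes with the P600
#' search when its first heartbeat-evoked component `[r + hep[1], r + hep[2]]`
#' intersects the P600 window `[p600[1], p600[2]]`. The set of such latencies
#' is the closed interval `[p600[1] - hep[2], p600[2] - hep[1]]` — with the
#' standard component timing (50-250 ms post-R, 530-750 ms post-target) this
#' is 280-700 ms.
#'
#' @param hep_component First HEP component, ms post-R (default `c(50, 250)`).
#' @param p600_window P600 search window, ms post-target (default
#'   `c(530, 750)`).
#' @return An object of class `overlap_window` with elements `lower`, `upper`
#'   (ms post-target) plus the two source windows.
#' @export
derive_overlap_window <- function(hep_component = c(50, 250),
                                  p600_window = c(530, 750)) {
  stopifnot(length(hep_component) == 2, length(p600_window) == 2)
  if (hep_component[1] > hep_component[2] || p600_window[1] > p600_window[2]) {
    stop("window pairs must be ordered", call. = FALSE)
  }
  lower <- p600_window[1] - hep_component[2]
  upper <- p600_window[2] - hep_component[1]
  if (lower >= upper) {
    stop("incompatible windows: derived overlap interval is empty",
         call. = FALSE)
  }
  structure(
    list(lower = lower, upper = upper,
         hep_component = hep_component, p600_window = p600_window),
    class = "overlap_window"
  )
}

#' @export
print.overlap_window <- function(x, ...) {
  cat(sprintf(
    "<overlap_window> R-peak latencies %g-%g ms post-target (HEP %g-%g ms post-R vs P600 %g-%g ms)\n",
    x$lower, x$upper, x$hep_component[1], x$hep_component[2],
    x$p600_window[1], x$p600_window[2]
  ))
  invisible(x)
}

#' Classify a single epoch by its R-peak latencies
#'
#' An epoch is labelled `"HEP"` if any R-peak latency (ms relative to target
#' onset) falls inside the closed overlap window, `"A-HEP"` otherwise. Beats
#' before the target have negative latencies and can never fall in the window.
#'
#' @param rpeak_latencies_ms Numeric vector of beat latencies for one epoch
#'   (may be empty).
#' @param window An [derive_overlap_window()] result.
#' @return `"HEP"` or `"A-HEP"`.
#' @export
partition_label <- function(rpeak_latencies_ms,
                            window = derive_overlap_window()) {
  if (length(rpeak_latencies_ms) > 0 &&
      any(rpeak_latencies_ms >= window$lower &
            rpeak_latencies_ms <= window$upper)) {
    "HEP"
  } else {
    "A-HEP"
  }
}

#' Partition an epoch set into heartbeat-affected and heartbeat-free epochs
#'
#' Applies [partition_label()] to every epoch's attached R-peak latencies and
#' stores the result in the epoch index.
#'
#' @param epochs An `eeg_epochs` object (see [extract_epochs()]).
#' @param window An [derive_overlap_window()] result.
#' @return The epoch set with an updated `label` column in `$info`.
#' @export
partition_epochs <- function(epochs, window = derive_overlap_window()) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epochs$info$label <- vapply(
    epochs$info$rpeak_latencies_ms,
    partition_label,
    character(1),
    window = window
  )
  epochs$window <- window
  epochs
}

#' Build the three partition conditions
#'
#' `ERP_T` contains every kept epoch; `ERP_HEP` the kept epochs whose R-peak
#' falls in the overlap window; `ERP_A-HEP` the rest. HEP and A-HEP are
#' disjoint and their union is ERP_T.
#'
#' @param epochs A partitioned, rejected `eeg_epochs` object.
#' @return Named list of logical epoch masks (`ERP_T`, `ERP_HEP`,
#'   `ERP_A-HEP`) with a `counts` attribute (tibble of per-partition epoch
#'   counts).
#' @export
build_condition_sets <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (any(is.na(epochs$info$label))) {
    stop("epochs must be partitioned first (see partition_epochs())",
         call. = FALSE)
  }
  kept <- epochs$info$kept
  sets <- list(
    ERP_T = kept,
    ERP_HEP = kept & epochs$info$label == "HEP",
    `ERP_A-HEP` = kept & epochs$info$label == "A-HEP"
  )
  attr(sets, "counts") <- tibble::tibble(
    partition = names(sets),
    n_epochs = vapply(sets, sum, integer(1))
  )
  sets
}
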