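#' Standardize a feature table
#'
#' Centers each feature to mean 0 and scales it to unit population SD
#' (`sqrt(mean((x - mean(x))^2)`), so the two-point feature `c(1, 3)` maps to
#' `c(-1, 1)`). When `stats` (a previous result) is supplied, its centers and
#' scales are applied instead — this is how test folds are standardized with
#' training-fold parameters.
#'
#' @param x Data frame or matrix of numeric features.
#' @param stats Optional result of a previous `standardize_features()` call.
#' @return List of class `feature_scaling`: `data` (standardized tibble),
#'   `center`, `scale`.
#' @export
standardize_features <- function(x, stats = NULL) {
  m <- as.matrix(x)
  if (nrow(m) < 2 && is.null(stats)) {
    stop("need at least 2 samples to standardize", call. = FALSE)
  }
  if (is.null(stats)) {
    center <- colMeans(m)
    scale <- sqrt(colMeans(sweep(m, 2, center, `-`)^2))
    if (any(scale == 0)) {
      stop("constant feature(s): ",
           paste(colnames(m)[scale == 0], collapse = ", "), call. = FALSE)
    }
  } else {
    center <- stats$center
    scale <- stats$scale
  }
  out <- sweep(sweep(m, 2, center, `-`), 2, scale, `/`)
  structure(
    list(data = tibble::as_tibble(as.data.frame(out)),
         center = center, scale = scale),
    class = "feature_scaling"
  )
}

#' Stratified cross-validation fold assignment
#'
#' Samples of each class are shuffled and dealt round-robin, so per-fold class
#' proportions differ from the global ones by at most one sample and the
#' folds are a disjoint cover. Deterministic given the seed.
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
make_stratified_folds <- function(labels, k, seed = 1) {
  n <- length(labels)
  if (k < 2 || k > n) stop("k must lie in [2, n]", call. = FALSE)
  fold <- integer(n)
  withr::with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Cross-validated RBF-SVM classification
#'
#' Radial-basis-function support vector machine with the kernel-scale
#' parameterization `k(a, b) = exp(-||a - b||^2 / (2 s^2))` (mapped onto
#' `gamma = 1 / (2 s^2)`), stratified k-fold cross-validation, per-fold
#' standardization fit on the training folds only, and metrics pooled over
#' the held-out folds.
#'
#' @param features Data frame/matrix of numeric features (samples x features).
#' @param labels Two-level class labels.
#' @param kernel_scale Kernel scale s (> 0).
#' @param spec A [classifier_spec()] for cost, folds, seed and positive class.
#' @return Object of class `mwl_svm_cv` with `predictions` (tibble: sample,
#'   fold, truth, predicted, score), `metrics`, `roc` (tibble of ROC points)
#'   and the configuration. `tidy()`, `glance()` and `autoplot()` methods are
#'   available.
#' @export
crossval_svm <- function(features, labels, kernel_scale = NULL,
                         spec = classifier_spec()) {
  m <- as.matrix(features)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (nrow(m) < spec$folds) {
    stop("fewer samples than folds", call. = FALSE)
  }
  if (is.null(kernel_scale)) {
    kernel_scale <- if (length(spec$kernel_scale) == 1) {
      spec$kernel_scale
    } else {
      stop("kernel_scale must be given when spec holds per-condition scales",
           call. = FALSE)
    }
  }
  positive <- spec$positive_class
  if (!positive %in% classes) positive <- classes[1]
  gamma <- 1 / (2 * kernel_scale^2)
  fold <- make_stratified_folds(labels, spec$folds, spec$seed)
  y <- factor(labels, levels = c(setdiff(classes, positive), positive))

  pred <- character(nrow(m))
  score <- numeric(nrow(m))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    # fold-level scaling: a feature that happens to be constant within a
    # training fold carries no information there and is left centred at 0
    mtr <- m[tr, , drop = FALSE]
    center <- colMeans(mtr)
    scale <- sqrt(colMeans(sweep(mtr, 2, center, `-`)^2))
    scale[scale == 0] <- 1
    sc <- list(center = center, scale = scale)
    te <- standardize_features(m[!tr, , drop = FALSE], stats = sc)
    sc$data <- standardize_features(mtr, stats = sc)$data
    fit <- e1071::svm(x = as.matrix(sc$data), y = y[tr],
                      kernel = "radial", gamma = gamma, cost = spec$cost,
                      scale = FALSE)
    p <- stats::predict(fit, as.matrix(te$data), decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # orient decision values so larger means more positive-class
    lab1 <- strsplit(colnames(dv)[1], "/")[[1]][1]
    s <- if (lab1 == positive) dv[, 1] else -dv[, 1]
    pred[!tr] <- as.character(p)
    score[!tr] <- s
  }

  metrics <- classification_metrics(labels, pred, score, positive)
  structure(
    list(
      predictions = tibble::tibble(
        sample = seq_len(nrow(m)), fold = fold,
        truth = labels, predicted = pred, score = score
      ),
      metrics = metrics$summary,
      confusion = metrics$confusion,
      roc = metrics$roc,
      kernel_scale = kernel_scale,
      cost = spec$cost,
      folds = spec$folds,
      positive_class = positive,
      seed = spec$seed,
      n = nrow(m)
    ),
    class = "mwl_svm_cv"
  )
}

#' @export
print.mwl_svm_cv <- function(x, ...) {
  cat(sprintf(
    "<mwl_svm_cv> RBF-SVM, kernel scale %.3g, %d-fold CV on %d samples\n",
    x$kernel_scale, x$folds, x$n))
  print(x$metrics)
  invisible(x)
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (recall on the positive class), specificity, and the
#' area under the ROC curve by trapezoidal integration over the decision
#' scores. Rates are in percent; ties in the scores are handled by grouping.
#'
#' @param y_true True labels (both classes must be present).
#' @param y_pred Predicted labels.
#' @param scores Decision scores, larger = more positive-class.
#' @param positive_class The positive class label.
#' @return List with `summary` (one-row tibble: accuracy, sensitivity,
#'   specificity, auc), `confusion` (2x2 table) and `roc` (tibble with `fpr`,
#'   `tpr`, `threshold`).
#' @export
classification_metrics <- function(y_true, y_pred, scores, positive_class) {
  if (length(y_true) != length(y_pred) || length(y_true) != length(scores)) {
    stop("y_true, y_pred and scores must have equal length", call. = FALSE)
  }
  pos <- y_true == positive_class
  if (!any(pos) || all(pos)) {
    stop("both classes must be present in y_true", call. = FALSE)
  }
  tp <- sum(pos & y_pred == positive_class)
  fn <- sum(pos & y_pred != positive_class)
  tn <- sum(!pos & y_pred != positive_class)
  fp <- sum(!pos & y_pred == positive_class)

  roc <- roc_points(scores, pos)
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

  list(
    summary = tibble::tibble(
      accuracy = 100 * (tp + tn) / length(y_true),
      sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      auc = auc
    ),
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(truth = c("positive", "negative"),
                                       predicted = c("positive", "negative"))),
    roc = roc
  )
}

roc_points <- function(scores, pos) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  tibble::tibble(
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1),
    threshold = c(Inf, thr, -Inf)
  )
}

#' Classify workload per partition condition
#'
#' Builds, for each partition (`ERP_T`, `ERP_HEP`, `ERP_A-HEP`), the
#' subject x condition sample matrix of post-minus-pre P600 features
#' (amplitude and latency per analysis electrode), then runs the
#' cross-validated RBF-SVM with the partition's kernel scale.
#'
#' @param diffs Feature-change tibble as produced by [feature_differences()].
#' @param spec A [classifier_spec()]; per-partition kernel scales are looked
#'   up by partition name (a scalar scale applies to all).
#' @param features Character vector of measures to use (default amplitude and
#'   latency).
#' @return List of class `mwl_classification`: `summary` (tibble with one row
#'   per partition: accuracy, sensitivity, specificity, auc) and `fits`
#'   (named list of `mwl_svm_cv` objects).
#' @export
classify_partitions <- function(diffs, spec = classifier_spec(),
                                features = c("amplitude", "latency")) {
  diffs <- diffs[diffs$measure %in% features, , drop = FALSE]
  parts <- unique(diffs$partition)
  fits <- list()
  for (p in parts) {
    wide <- tidyr::pivot_wider(
      diffs[diffs$partition == p, c("subject", "condition", "electrode",
                                    "measure", "value")],
      names_from = c("measure", "electrode"),
      values_from = "value"
    )
    m <- as.matrix(wide[, setdiff(names(wide), c("subject", "condition"))])
    ks <- if (length(spec$kernel_scale) == 1) {
      unname(spec$kernel_scale)
    } else if (p %in% names(spec$kernel_scale)) {
      unname(spec$kernel_scale[[p]])
    } else {
      stop(sprintf("no kernel scale for partition '%s'", p), call. = FALSE)
    }
    fits[[p]] <- crossval_svm(m, wide$condition, kernel_scale = ks,
                              spec = spec)
  }
  summary <- dplyr::bind_rows(
    lapply(fits, function(f) f$metrics), .id = "partition"
  )
  structure(list(summary = summary, fits = fits),
            class = "mwl_classification")
}

#' @export
print.mwl_classification <- function(x, ...) {
  cat("<mwl_classification> cross-validated RBF-SVM per partition\n")
  print(x$summary)
  invisible(x)
}
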