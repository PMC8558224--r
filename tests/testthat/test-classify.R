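test_that("standardization uses the population SD and is reusable", {
  two <- standardize_features(data.frame(f = c(1, 3)))
  expect_equal(two$data$f, c(-1, 1))
  # idempotence
  set.seed(1)
  m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  once <- standardize_features(m)
  twice <- standardize_features(as.matrix(once$data))
  expect_equal(as.matrix(twice$data), as.matrix(once$data), tolerance = 1e-12)
  # applying train statistics to new data
  te <- standardize_features(m + 5, stats = once)
  expect_equal(as.matrix(te$data),
               sweep(as.matrix(once$data), 2, 5 / once$scale, `+`),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(standardize_features(cbind(x = rep(2, 5))), "x")
})

test_that("stratified folds cover the samples and balance the classes", {
  labels <- rep(c("low", "high"), each = 14)
  fold <- make_stratified_folds(labels, 10, seed = 4)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 28)
  # class proportions per fold differ from global by at most one sample
  tab <- table(fold, labels)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  expect_identical(make_stratified_folds(labels, 10, seed = 4), fold)
  expect_error(make_stratified_folds(labels, 1), "\\[2, n\\]")
})

test_that("well-separated clusters classify perfectly", {
  set.seed(5)
  x <- rbind(matrix(rnorm(28, 0, 1), 14, 2),
             matrix(rnorm(28, 10, 1), 14, 2))
  colnames(x) <- c("f1", "f2")
  labels <- rep(c("low", "high"), each = 14)
  fit <- crossval_svm(x, labels, kernel_scale = 2,
                      spec = classifier_spec(seed = 1))
  expect_equal(fit$metrics$accuracy, 100)
  expect_equal(fit$metrics$sensitivity, 100)
  expect_equal(fit$metrics$specificity, 100)
  expect_equal(fit$metrics$auc, 1)
})

test_that("permuted labels give chance-level accuracy on average", {
  set.seed(6)
  x <- matrix(rnorm(28 * 4), 28, 4)
  colnames(x) <- paste0("f", 1:4)
  accs <- sapply(1:200, function(r) {
    labels <- sample(rep(c("low", "high"), each = 14))
    crossval_svm(x, labels, kernel_scale = 2,
                 spec = classifier_spec(seed = r))$metrics$accuracy
  })
  expect_gt(mean(accs), 45)
  expect_lt(mean(accs), 55)
})

test_that("metrics match confusion-matrix arithmetic", {
  y <- rep(c("high", "low"), each = 14)
  pred <- c(rep("high", 9), rep("low", 5),    # 9/14 positives correct
            rep("low", 11), rep("high", 3))   # 11/14 negatives correct
  set.seed(7)
  scores <- ifelse(pred == "high", 1, -1) + rnorm(28, 0, 0.1)
  m <- classification_metrics(y, pred, scores, "high")
  expect_equal(m$summary$sensitivity, 100 * 9 / 14, tolerance = 1e-9)
  expect_equal(m$summary$specificity, 100 * 11 / 14, tolerance = 1e-9)
  expect_equal(m$summary$accuracy, 100 * 20 / 28, tolerance = 1e-9)
  expect_equal(sum(m$confusion), 28)
  expect_error(classification_metrics(rep("a", 4), rep("a", 4), 1:4, "a"),
               "both classes")
})

test_that("constant scores give an uninformative ROC and AUC one half", {
  y <- rep(c("high", "low"), each = 5)
  m <- classification_metrics(y, y, rep(0, 10), "high")
  expect_equal(m$summary$auc, 0.5)
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  library(pROC)
  set.seed(8)
  y <- rep(c("high", "low"), each = 25)
  scores <- rnorm(50) + (y == "high")
  m <- classification_metrics(y, ifelse(scores > 0.5, "high", "low"),
                              scores, "high")
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                        levels = c("low", "high"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(m$summary$auc, ref, tolerance = 1e-10)
})

test_that("accuracy on 28 samples is quantized to 1/28 and order-invariant", {
  set.seed(9)
  x <- matrix(rnorm(28 * 3), 28, 3)
  colnames(x) <- paste0("f", 1:3)
  labels <- rep(c("low", "high"), each = 14)
  fit <- crossval_svm(x, labels, kernel_scale = 2,
                      spec = classifier_spec(seed = 2))
  k <- fit$metrics$accuracy * 28 / 100
  expect_equal(k, round(k), tolerance = 1e-9)
  # broom-style accessors
  expect_equal(nrow(tidy(fit)), 28)
  expect_equal(glance(fit)$folds, 10)
  expect_error(crossval_svm(x, rep("low", 28), kernel_scale = 2),
               "two classes")
})
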