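#' Hedges' g from group summaries
#'
#' Standardized mean difference `(m2 - m1) / s_pooled` with the pooled
#' standard deviation `s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) /
#' (n1 + n2 - 2))`, which reduces to `sqrt((sd1^2 + sd2^2) / 2)` for equal
#' group sizes. The ordering convention is second minus first group, so for a
#' low/high workload comparison pass the low condition first to obtain a
#' high-minus-low effect.
#'
#' By default no small-sample correction is applied; set
#' `small_sample_correction = TRUE` for the classical
#' `J = 1 - 3 / (4 (n1 + n2) - 9)` multiplier.
#'
#' @param m1,sd1,n1 Mean, SD and size of the first group.
#' @param m2,sd2,n2 Mean, SD and size of the second group.
#' @param small_sample_correction Apply the J correction (default `FALSE`).
#' @return Hedges' g (numeric scalar; vectorized over its arguments).
#' @export
hedges_g <- function(m1, sd1, m2, sd2, n1 = 14, n2 = n1,
                     small_sample_correction = FALSE) {
  if (any(sd1 < 0) || any(sd2 < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("group sizes must be at least 2", call. = FALSE)
  }
  if (any(sd1 == 0 & sd2 == 0)) {
    stop("both standard deviations are zero: effect size undefined",
         call. = FALSE)
  }
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  g <- (m2 - m1) / sp
  if (small_sample_correction) {
    g <- g * (1 - 3 / (4 * (n1 + n2) - 9))
  }
  g
}

#' Normal-approximation confidence interval for Hedges' g
#'
#' `g +/- z * SE` with `SE = sqrt((n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2)))`,
#' the large-sample variance of a standardized mean difference.
#'
#' @param g Effect size.
#' @param n1,n2 Group sizes.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Tibble with columns `g`, `se`, `lower`, `upper`, `level`.
#' @export
g_confidence_interval <- function(g, n1 = 14, n2 = n1, level = 0.95) {
  if (any(level <= 0) || any(level >= 1)) {
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("group sizes must be at least 2", call. = FALSE)
  }
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(g = g, se = se, lower = g - z * se, upper = g + z * se,
                 level = level)
}

#' Paired comparison with a normality gate
#'
#' Tests the paired differences `y - x`. A Shapiro-Wilk test on the
#' differences decides the route: if normality is not rejected at
#' `alpha_gate`, a two-tailed paired t-test (df = n - 1) is used; otherwise a
#' Wilcoxon signed-rank test is reported with `method = "wilcoxon"`.
#'
#' @param x,y Paired observations (e.g. low- and high-workload features);
#'   the difference is `y - x`.
#' @param alpha_gate Significance level of the normality gate (0.05).
#' @return One-row tibble: `method`, `n`, `statistic`, `df`, `p_value`,
#'   `mean_diff`, `sd_diff`, `shapiro_p`, `normal`.
#' @export
paired_test <- function(x, y, alpha_gate = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("paired test needs at least 3 pairs", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0) {
    stop("paired differences have zero variance: test degenerate",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(d)
  normal <- sw$p.value >= alpha_gate
  if (normal) {
    tt <- stats::t.test(y, x, paired = TRUE)
    tibble::tibble(
      method = "paired t", n = n,
      statistic = unname(tt$statistic), df = n - 1,
      p_value = tt$p.value,
      mean_diff = mean(d), sd_diff = stats::sd(d),
      shapiro_p = sw$p.value, normal = TRUE
    )
  } else {
    wt <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE)
    tibble::tibble(
      method = "wilcoxon", n = n,
      statistic = unname(wt$statistic), df = NA_real_,
      p_value = wt$p.value,
      mean_diff = mean(d), sd_diff = stats::sd(d),
      shapiro_p = sw$p.value, normal = FALSE
    )
  }
}

#' Bonferroni-corrected significance level
#'
#' @param base_alpha Family-wise level (0.05).
#' @param family_size Number of hypotheses in the family.
#' @return List of class `bonferroni_alpha` with `alpha` (full precision),
#'   `alpha_4dp` (rounded to 4 decimals, the conventional reporting
#'   precision), `base_alpha` and `family_size`.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, family_size) {
  if (family_size < 1) stop("family_size must be at least 1", call. = FALSE)
  if (base_alpha <= 0 || base_alpha >= 1) {
    stop("base_alpha must lie in (0, 1)", call. = FALSE)
  }
  a <- base_alpha / family_size
  structure(
    list(alpha = a, alpha_4dp = round(a, 4),
         base_alpha = base_alpha, family_size = family_size),
    class = "bonferroni_alpha"
  )
}

#' @export
print.bonferroni_alpha <- function(x, ...) {
  cat(sprintf("Bonferroni: alpha = %g / %d = %.4g (%.4f at 4 dp)\n",
              x$base_alpha, x$family_size, x$alpha, x$alpha_4dp))
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection on the covariates (plus intercept). The p-value uses the
#' t-distribution with `n - k - 2` degrees of freedom, k the number of
#' covariates.
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame or matrix of covariates (same number of rows).
#' @return One-row tibble: `r_partial`, `statistic`, `df`, `p_value`, `n`,
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(z)
  if (length(y) != n || nrow(z) != n) {
    stop("x, y and covariates must have the same length", call. = FALSE)
  }
  if (n < k + 3) {
    stop("need at least n_covariates + 3 observations", call. = FALSE)
  }
  design <- cbind(1, z)
  qz <- qr(design)
  if (qz$rank < ncol(design)) {
    # constant covariates are harmless (absorbed by the intercept);
    # genuinely collinear ones are an error
    keep <- qz$pivot[seq_len(qz$rank)]
    dropped <- setdiff(seq_len(ncol(design)), keep)
    non_constant <- vapply(dropped, function(j) {
      j > 1 && stats::sd(design[, j]) > 0
    }, logical(1))
    if (any(non_constant)) {
      stop("covariates are collinear", call. = FALSE)
    }
    design <- design[, keep, drop = FALSE]
    qz <- qr(design)
  }
  rx <- stats::residuals(stats::lm.fit(design, x))
  ry <- stats::residuals(stats::lm.fit(design, y))
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tt <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r_partial = r, statistic = tt, df = df,
    p_value = 2 * stats::pt(-abs(tt), df),
    n = n, n_covariates = k
  )
}

#' Minimal detectable paired effect size (sensitivity)
#'
#' Solves `power(dz) = power` for the paired-design standardized effect size
#' dz under the noncentral t distribution with `df = n - 1` and noncentrality
#' `dz * sqrt(n)`.
#'
#' @param n Number of pairs.
#' @param alpha Significance level (0.05).
#' @param power Target power (0.80).
#' @param two_tailed Two-tailed test (default `TRUE`).
#' @return The minimal detectable dz.
#' @export
sensitivity_dz <- function(n, alpha = 0.05, power = 0.80, two_tailed = TRUE) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (power <= 0 || power >= 1) {
    stop("power must lie strictly between 0 and 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  df <- n - 1
  tc <- stats::qt(1 - alpha / (1 + two_tailed), df)
  pw <- function(dz) {
    ncp <- dz * sqrt(n)
    p <- 1 - stats::pt(tc, df, ncp = ncp)
    if (two_tailed) p <- p + stats::pt(-tc, df, ncp = ncp)
    p
  }
  stats::uniroot(function(dz) pw(dz) - power, c(1e-8, 20), tol = 1e-10)$root
}

#' Paired effect-size report over a feature table
#'
#' For every partition x measure x electrode cell, compares the
#' post-minus-pre feature change between the low and high workload conditions
#' across subjects: paired test ([paired_test()]), Hedges' g from the two
#' condition summaries (high minus low), its 95% CI, and the Bonferroni
#' verdict within the `8 electrodes x 2 measures = 16`-hypothesis family of
#' each partition.
#'
#' @param diffs Tidy tibble of per-subject feature changes with columns
#'   `subject`, `condition` (`"low"` / `"high"`), `partition`, `electrode`,
#'   `measure` (`"amplitude"` / `"latency"`) and `value` (see
#'   [feature_differences()]).
#' @param base_alpha Family-wise significance level (0.05).
#' @param family_size Hypotheses per family; default the number of
#'   electrode x measure cells within each partition.
#' @return Tibble of class `effect_size_report`, one row per cell, mirroring
#'   a summary-table layout: group means/SDs, t, p, g, CI and significance.
#' @export
effect_size_report <- function(diffs, base_alpha = 0.05, family_size = NULL) {
  required <- c("subject", "condition", "partition", "electrode",
                "measure", "value")
  if (!all(required %in% names(diffs))) {
    stop("diffs must contain columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(family_size)) {
    family_size <- nrow(dplyr::distinct(diffs, .data$electrode, .data$measure))
  }
  alpha_fam <- bonferroni_alpha(base_alpha, family_size)$alpha

  wide <- tidyr::pivot_wider(diffs, names_from = "condition",
                             values_from = "value")
  out <- dplyr::group_modify(
    dplyr::group_by(wide, .data$partition, .data$measure, .data$electrode),
    function(d, key) {
      # fewer than 3 pairs: the normality-gated test is undefined, so only
      # the descriptive effect size is reported
      test <- if (nrow(d) >= 3) {
        paired_test(d$low, d$high)
      } else {
        tibble::tibble(statistic = NA_real_, df = NA_real_,
                       p_value = NA_real_, method = "none (n < 3)")
      }
      g <- hedges_g(mean(d$low), stats::sd(d$low),
                    mean(d$high), stats::sd(d$high),
                    n1 = max(nrow(d), 2), n2 = max(nrow(d), 2))
      ci <- g_confidence_interval(g, max(nrow(d), 2), max(nrow(d), 2))
      tibble::tibble(
        n = nrow(d),
        mean_low = mean(d$low), sd_low = stats::sd(d$low),
        mean_high = mean(d$high), sd_high = stats::sd(d$high),
        t = test$statistic, df = test$df, p = test$p_value,
        method = test$method,
        g = g, ci_lower = ci$lower, ci_upper = ci$upper
      )
    }
  )
  out <- dplyr::ungroup(out)
  out$alpha_family <- alpha_fam
  out$significant <- out$p < alpha_fam
  class(out) <- c("effect_size_report", class(out))
  out
}

#' Partial-correlation report between post-task features and SMEQ scores
#'
#' For every partition x measure x electrode cell, the partial correlation
#' between the post-task feature and the post-task SMEQ score across all
#' subject x condition samples, controlling for the pre-task feature and the
#' pre-task SMEQ score.
#'
#' @param features Session-level feature table (see [cohort_features()]) with
#'   columns `subject`, `condition`, `session` (`"pre"`/`"post"`),
#'   `partition`, `electrode`, `measure`, `value`, `smeq`.
#' @return Tibble, one row per cell: `r_partial`, `p_value`, `n`.
#' @export
correlation_report <- function(features) {
  wide <- tidyr::pivot_wider(
    features,
    id_cols = c("subject", "condition", "partition", "electrode", "measure"),
    names_from = "session",
    values_from = c("value", "smeq")
  )
  out <- dplyr::group_modify(
    dplyr::group_by(wide, .data$partition, .data$measure, .data$electrode),
    function(d, key) {
      if (nrow(d) < 5) {
        # too few samples to control two covariates
        return(tibble::tibble(r_partial = NA_real_, p_value = NA_real_,
                              n = nrow(d)))
      }
      pc <- partial_correlation(
        d$value_post, d$smeq_post,
        covariates = cbind(pre_feature = d$value_pre, pre_smeq = d$smeq_pre)
      )
      tibble::tibble(r_partial = pc$r_partial, p_value = pc$p_value, n = pc$n)
    }
  )
  dplyr::ungroup(out)
}
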