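# Diagnostic-accuracy statistics: threshold rules, 2x2 confusion metrics,
# Fisher's exact test, rank and binary-marker AUC, correlations, group
# comparisons, and Bland-Altman inter-observer agreement.

#' Threshold rule for a continuous metric
#'
#' A dichotomising rule: test-positive when the metric is `>= cutpoint`
#' (`"GE_POSITIVE"`, e.g. ventricular mass index >= 0.4) or `<= cutpoint`
#' (`"LE_POSITIVE"`, e.g. TAPSE <= 2 cm).  Boundaries are inclusive.
#'
#' @param metric metric (column) name.
#' @param cutpoint numeric threshold.
#' @param direction `"GE_POSITIVE"` or `"LE_POSITIVE"`.
#' @return an object of class `threshold_rule`.
#' @export
threshold_rule <- function(metric, cutpoint,
                           direction = c("GE_POSITIVE", "LE_POSITIVE")) {
  direction <- match.arg(direction)
  stopifnot(is.character(metric), length(metric) == 1,
            is.numeric(cutpoint), length(cutpoint) == 1)
  structure(list(metric = metric, cutpoint = cutpoint,
                 direction = direction), class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  op <- if (x$direction == "GE_POSITIVE") ">=" else "<="
  cat(sprintf("<threshold_rule> positive when %s %s %g\n",
              x$metric, op, x$cutpoint))
  invisible(x)
}

#' Apply a threshold rule to metric values
#'
#' @param rule a [threshold_rule()].
#' @param values numeric vector of metric values; `NA` values (metric not
#'   measured) stay `NA` and are excluded from downstream counts rather
#'   than raising an error.
#' @return logical vector, `TRUE` = test-positive.
#' @export
classify <- function(rule, values) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (rule$direction == "GE_POSITIVE") values >= rule$cutpoint
  else values <= rule$cutpoint
}

#' Diagnostic accuracy from a 2x2 table
#'
#' Sensitivity, specificity and predictive values from test-vs-disease
#' counts, plus the two-sided Fisher exact p-value and the binary-marker
#' AUC.  Internal values are kept at full precision; the printed report
#' rounds percentages half-up to integers and the AUC to two decimals,
#' the precision used in clinical accuracy tables.
#'
#' @param tp,fp,fn,tn non-negative counts: true/false positives/negatives
#'   with respect to catheter-confirmed disease.
#' @return an object of class `diagnostic_result`: counts plus
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percent, full precision),
#'   `auc` and `fisher_p`.  `ppv` is `NA` when no test-positives exist.
#' @export
#' @examples
#' confusion_metrics(tp = 108, fp = 2, fn = 20, tn = 29)
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rhcmr_error("counts must be non-negative integers", "rhcmr_invalid_counts")
  }
  if (tp + fn == 0 || fp + tn == 0) {
    rhcmr_error("need at least one diseased and one non-diseased subject",
                "rhcmr_invalid_counts")
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (fp + tn),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    auc = binary_test_auc(tp, fp, fn, tn),
    fisher_p = fisher_exact_p(tp, fp, fn, tn)),
    class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("<diagnostic_result>\n")
  cat(sprintf("  counts: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sens %d%%  spec %d%%  PPV %s%%  NPV %s%%  AUC %.2f  Fisher p %s\n",
              round_half_up(x$sensitivity), round_half_up(x$specificity),
              if (is.na(x$ppv)) "NA" else round_half_up(x$ppv),
              if (is.na(x$npv)) "NA" else round_half_up(x$npv),
              x$auc, format.pval(x$fisher_p, digits = 3)))
  invisible(x)
}

#' Predictive values reconstructed from sensitivity, specificity and group sizes
#'
#' Bayes-consistent reconstruction: with `n_pos` diseased and `n_neg`
#' non-diseased subjects, a test with the given sensitivity and specificity
#' produces `tp = sens * n_pos` and `fp = (1 - spec) * n_neg` expected
#' positives, from which PPV and NPV follow.  Useful for recomputing
#' accuracy-table rows when only the summary operating point is printed.
#'
#' @param sensitivity,specificity percent.
#' @param n_pos,n_neg disease-positive and disease-negative group sizes.
#' @return named numeric vector `c(ppv =, npv =)` in percent, full
#'   precision.
#' @export
#' @examples
#' predictive_values(81, 88, n_pos = 194, n_neg = 39)  # PPV ~97%
predictive_values <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- sensitivity / 100 * n_pos
  fn <- n_pos - tp
  fp <- (1 - specificity / 100) * n_neg
  tn <- n_neg - fp
  c(ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' With both margins fixed, sums the hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table (the
#' standard two-sided convention, with a 1e-7 relative tolerance on the
#' comparison to absorb floating-point noise).  Degenerate margins give
#' p = 1.
#'
#' @inheritParams confusion_metrics
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    rhcmr_error("counts must be non-negative integers", "rhcmr_invalid_counts")
  }
  m <- tp + fn       # diseased column total
  n <- fp + tn       # non-diseased column total
  k <- tp + fp       # test-positive row total
  if (m == 0 || n == 0 || k == 0 || (fn + tn) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tp, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve as the probability that a randomly chosen
#' diseased subject has a more disease-like value than a randomly chosen
#' non-diseased subject, computed from midranks (ties count 1/2).  The
#' direction is declared per metric, not inferred: `"GE_POSITIVE"` means
#' high values indicate disease, `"LE_POSITIVE"` means low values do.
#' Invariant under strictly monotone transforms of the values.
#'
#' @param values numeric metric values; pairs with `NA` in `values` or
#'   `labels` are dropped.
#' @param labels logical (or 0/1) disease labels, `TRUE` = diseased.
#' @param direction `"GE_POSITIVE"` or `"LE_POSITIVE"`.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(values, labels, direction = c("GE_POSITIVE",
                                                  "LE_POSITIVE")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    rhcmr_error("both classes must be present", "rhcmr_invalid_labels")
  }
  if (direction == "LE_POSITIVE") values <- -values
  r <- rank(values)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC of a binary test from its 2x2 counts
#'
#' A dichotomous marker has a two-point ROC curve whose area is
#' (sensitivity + specificity) / 2 on the proportion scale.  Equals
#' [roc_auc()] applied to the 0/1 marker exactly.
#'
#' @inheritParams confusion_metrics
#' @return AUC in [0, 1], full precision (report at 2 decimals).
#' @export
#' @examples
#' binary_test_auc(108, 2, 20, 29)  # ~0.89
binary_test_auc <- function(tp, fp, fn, tn) {
  (tp / (tp + fn) + tn / (fp + tn)) / 2
}

#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation; p from the t statistic with n - 2 degrees of
#' freedom.  Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors of equal length (n >= 3 complete pairs).
#' @return named numeric vector `c(r =, p =, n =)`.
#' @export
pearson_r <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    rhcmr_error("need at least 3 complete pairs", "rhcmr_invalid_pairs")
  }
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-group and multi-group comparisons
#'
#' Continuous data in two groups: independent t-test, pooled-variance
#' Student by default (`welch = TRUE` switches to Welch).  Categorical
#' data: chi-square test on the contingency table.  More than two groups:
#' one-way ANOVA followed by Bonferroni-adjusted pairwise t-tests (the
#' adjustment factor is the number of pairwise comparisons).
#'
#' @param values numeric (continuous) or factor/character (categorical)
#'   observations; `NA`s dropped pairwise with `groups`.
#' @param groups group labels, coerced to factor.
#' @param type `"continuous"` or `"categorical"`; default guesses from
#'   `values`.
#' @param welch use Welch's unequal-variance t-test for two groups.
#' @return a list of class `group_comparison` with elements `method`,
#'   `p_value`, and for ANOVA a `pairwise` matrix of adjusted p-values.
#' @export
group_compare <- function(values, groups, type = NULL, welch = FALSE) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (is.null(type)) {
    type <- if (is.numeric(values)) "continuous" else "categorical"
  }
  type <- match.arg(type, c("continuous", "categorical"))
  ng <- nlevels(groups)
  if (type == "categorical") {
    tt <- chisq.test(table(values, groups))
    out <- list(method = "chi-square", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else if (ng == 2) {
    tt <- t.test(values ~ groups, var.equal = !welch)
    out <- list(method = if (welch) "Welch t" else "Student t",
                statistic = unname(tt$statistic), p_value = tt$p.value)
  } else if (ng > 2) {
    fit <- aov(values ~ groups)
    p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni")
    out <- list(method = "one-way ANOVA + Bonferroni pairwise t",
                p_value = p_overall, pairwise = pw$p.value)
  } else {
    rhcmr_error("need at least 2 groups", "rhcmr_invalid_groups")
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: p = %s\n", x$method,
              format.pval(x$p_value, digits = 3)))
  if (!is.null(x$pairwise)) {
    cat("  Bonferroni-adjusted pairwise p-values:\n")
    print(signif(x$pairwise, 3))
  }
  invisible(x)
}

#' Bland-Altman agreement between two observers
#'
#' Differences `obs1 - obs2`: bias is the mean difference, and the 95%
#' limits of agreement are bias +/- 1.96 x SD of the differences.
#'
#' @param obs1,obs2 paired measurements (equal length, n >= 2); pairs with
#'   missing values are dropped.
#' @return an object of class `agreement_result` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and the per-pair `means`/`diffs` used for
#'   plotting.
#' @export
bland_altman <- function(obs1, obs2) {
  keep <- complete.cases(obs1, obs2)
  obs1 <- obs1[keep]; obs2 <- obs2[keep]
  if (length(obs1) < 2) {
    rhcmr_error("need at least 2 complete pairs", "rhcmr_invalid_pairs")
  }
  d <- obs1 - obs2
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), means = (obs1 + obs2) / 2, diffs = d),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d: bias %.3g (SD %.3g), 95%% limits of agreement %.3g to %.3g\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.agreement_result <- function(x, ...) {
  plot(x$means, x$diffs, xlab = "Mean of observers",
       ylab = "Difference (obs1 - obs2)", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}
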