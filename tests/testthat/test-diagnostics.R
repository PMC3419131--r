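# Diagnostic-accuracy statistics: rules, confusion metrics, Fisher exact,
# AUC, correlations, group tests and agreement.

test_that("threshold rules are boundary-inclusive in the declared direction", {
  ge <- threshold_rule("vmi", 0.4, "GE_POSITIVE")
  expect_identical(classify(ge, c(0.41, 0.40, 0.39)),
                   c(TRUE, TRUE, FALSE))
  le <- threshold_rule("tapse", 2, "LE_POSITIVE")
  expect_identical(classify(le, c(2.0, 2.01)), c(TRUE, FALSE))
  expect_true(is.na(classify(ge, NA_real_)))
})

test_that("confusion metrics reproduce definitional identities", {
  cm <- confusion_metrics(tp = 108, fp = 2, fn = 20, tn = 29)
  expect_equal(round_half_up(cm$ppv), 98)
  expect_equal(cm$sensitivity, 100 * 108 / 128)
  expect_equal(cm$specificity, 100 * 29 / 31)
  expect_equal(cm$npv, 100 * 29 / 49)

  sym <- confusion_metrics(10, 7, 10, 7)
  expect_equal(sym$sensitivity, 50)
  expect_equal(sym$specificity, 50)

  perfect <- confusion_metrics(20, 0, 0, 15)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv), c(100, 100, 100, 100))
  expect_equal(perfect$auc, 1)

  expect_error(confusion_metrics(-1, 0, 1, 1), class = "rhcmr_invalid_counts")
  expect_error(confusion_metrics(0, 0, 0, 5), class = "rhcmr_invalid_counts")
})

test_that("PPV is Bayes-consistent with sensitivity, specificity and prevalence", {
  set.seed(12)
  for (i in 1:50) {
    tab <- rpois(4, 20) + 1
    cm <- confusion_metrics(tab[1], tab[2], tab[3], tab[4])
    s <- cm$sensitivity / 100; c_ <- cm$specificity / 100
    p <- (tab[1] + tab[3]) / sum(tab)
    expect_equal(cm$ppv / 100, s * p / (s * p + (1 - c_) * (1 - p)),
                 tolerance = 1e-12)
  }
})

test_that("predictive values reconstructed from an operating point match counts", {
  pv <- predictive_values(81, 88, n_pos = 194, n_neg = 39)
  expect_equal(round_half_up(pv[["ppv"]]), 97)
  pv2 <- predictive_values(83, 84, n_pos = 194, n_neg = 39)
  expect_equal(round_half_up(pv2[["ppv"]]), 96)
  # with integer-consistent counts the reconstruction is exact
  cm <- confusion_metrics(108, 2, 20, 29)
  pv3 <- predictive_values(cm$sensitivity, cm$specificity, 128, 31)
  expect_equal(pv3[["ppv"]], cm$ppv)
})

test_that("Fisher exact p matches frozen enumerated values", {
  # 34/70 by direct enumeration of the 2x2 tables with margins (4,4)/(4,4)
  expect_equal(fisher_exact_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  # degenerate margin: a single possible table
  expect_equal(fisher_exact_p(0, 0, 7, 5), 1)
  # perfectly separated 10/10: doubled single-tail 2/choose(20,10)
  expect_equal(fisher_exact_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_lt(fisher_exact_p(10, 0, 0, 10), 0.001)
})

test_that("Fisher exact agrees with enumeration for every table up to n = 30", {
  tabs <- as.matrix(expand.grid(a = 0:30, b = 0:30, c = 0:30, d = 0:30))
  tabs <- tabs[rowSums(tabs) <= 30 & rowSums(tabs) > 0, , drop = FALSE]
  p_impl <- vapply(seq_len(nrow(tabs)), function(i) {
    fisher_exact_p(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
  }, numeric(1))
  p_enum <- vapply(seq_len(nrow(tabs)), function(i) {
    fisher_enum(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
  }, numeric(1))
  expect_equal(nrow(tabs), choose(34, 4) - 1)  # every non-empty table
  expect_equal(p_impl, p_enum, tolerance = 1e-9)
})

test_that("Fisher exact agrees with stats::fisher.test", {
  set.seed(8)
  for (i in 1:100) {
    t4 <- rpois(4, 6)
    if (sum(t4) == 0) next
    expect_equal(fisher_exact_p(t4[1], t4[2], t4[3], t4[4]),
                 stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("rank AUC handles separation, ties and declared direction", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                       "GE_POSITIVE"), 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5), "GE_POSITIVE"),
               0.5)
  # lower-is-disease metrics flip via the declared direction, not the data
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(TRUE, FALSE), each = 3),
                       "LE_POSITIVE"), 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5), "GE_POSITIVE"),
               class = "rhcmr_invalid_labels")
})

test_that("binary-marker rank AUC equals (sens + spec) / 2 exactly", {
  expect_equal(binary_test_auc(108, 2, 20, 29), (108 / 128 + 29 / 31) / 2)
  expect_equal(round_half_up(binary_test_auc(108, 2, 20, 29), 2), 0.89)
  # useless test: sens = 1 - spec
  expect_equal(binary_test_auc(30, 30, 70, 70), 0.5)
  expect_equal(binary_test_auc(10, 0, 0, 10), 1)
  set.seed(21)
  for (i in 1:25) {
    t4 <- rpois(4, 15) + 1
    marker <- rep(c(1, 1, 0, 0), times = t4)
    disease <- rep(c(TRUE, FALSE, TRUE, FALSE), times = t4)
    expect_equal(roc_auc(marker, disease, "GE_POSITIVE"),
                 binary_test_auc(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(5)
  v <- rnorm(60); lab <- rbinom(60, 1, 0.4) == 1
  a0 <- roc_auc(v, lab, "GE_POSITIVE")
  expect_equal(roc_auc(exp(v), lab, "GE_POSITIVE"), a0)
  expect_equal(roc_auc(v^3, lab, "GE_POSITIVE"), a0)
  expect_equal(roc_auc(rank(v), lab, "GE_POSITIVE"), a0)
})

test_that("rank AUC agrees with pROC on continuous data", {
  skip_if_not_installed("pROC")
  set.seed(14)
  v <- rnorm(80); lab <- rbinom(80, 1, 0.5)
  a <- roc_auc(v, lab == 1, "GE_POSITIVE")
  p <- suppressMessages(pROC::auc(pROC::roc(lab, v, direction = "<",
                                            quiet = TRUE)))
  expect_equal(a, as.numeric(p), tolerance = 1e-12)
})

test_that("Pearson correlation handles affine cases and sampling variability", {
  x <- 1:20
  expect_equal(pearson_r(x, 2 * x + 1)[["r"]], 1)
  expect_equal(pearson_r(x, -x)[["r"]], -1)
  expect_error(pearson_r(1:2, 1:2), class = "rhcmr_invalid_pairs")

  # bivariate normal with rho = 0.78 at n = 233: r should stay within the
  # Fisher-z 99.5% band around the target for nearly all seeds
  rho <- 0.78; n <- 233
  inside <- 0
  for (s in 1:100) {
    set.seed(s)
    z <- rnorm(n); e <- rnorm(n)
    y <- rho * z + sqrt(1 - rho^2) * e
    r <- pearson_r(z, y)[["r"]]
    if (r >= 0.70 && r <= 0.84) inside <- inside + 1
  }
  expect_gte(inside, 95)
})

test_that("group comparisons dispatch to t, chi-square and Bonferroni ANOVA", {
  g <- rep(c("A", "B"), each = 10)
  same <- rep(1:10, 2)
  expect_equal(group_compare(same, g)$p_value, 1)

  set.seed(2)
  shifted <- c(rnorm(50), rnorm(50, 5))
  expect_lt(group_compare(shifted, rep(c("A", "B"), each = 50))$p_value,
            0.001)

  cat_tab <- group_compare(rep(c("yes", "no"), c(30, 70)),
                           rep(c("A", "B"), 50), type = "categorical")
  expect_match(cat_tab$method, "chi-square")

  five <- group_compare(rnorm(100), rep(letters[1:5], each = 20))
  expect_match(five$method, "ANOVA")
  # C(5,2) = 10 pairwise Bonferroni comparisons in the lower triangle
  expect_equal(sum(!is.na(five$pairwise)), 10)
})

test_that("Bland-Altman limits are bias +/- 1.96 SD of the differences", {
  set.seed(77)
  d <- as.numeric(scale(rnorm(40))) * 10.8 + (-2.1)  # exact mean/SD
  ba <- bland_altman(d, rep(0, 40))
  expect_equal(ba$bias, -2.1, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 10.8, tolerance = 1e-12)
  expect_equal(ba$loa_low, -2.1 - 1.96 * 10.8, tolerance = 1e-12)
  expect_equal(round_half_up(ba$loa_low, 1), -23.3)
  expect_equal(round_half_up(ba$loa_high, 1), 19.1)

  same <- bland_altman(1:10, 1:10)
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))

  off <- bland_altman((1:10) + 3, 1:10)
  expect_equal(off$bias, 3)
  expect_equal(off$sd_diff, 0)
})
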