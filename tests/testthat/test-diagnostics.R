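# Evaluation layer: contingency statistics, ROC sweep, ANOVA/LSD, Hedges' g.

# the published per-category counts: improved/total by criteria count
published_counts <- function() {
  data.frame(criteria_met = 0:3,
             n_improved = c(6, 22, 14, 8),
             n_total = c(16, 36, 15, 8))
}

test_that("contingency at k = 2 reproduces the published 2x2 table", {
  ct <- build_contingency(published_counts(), k = 2)
  expect_equal(ct, list(tp = 22, fp = 1, fn = 28, tn = 24))
  ct0 <- build_contingency(published_counts(), k = 0)
  expect_equal(ct0$fn, 0)
  expect_equal(ct0$tn, 0)
  expect_error(build_contingency(published_counts(), k = 5),
               "between 0 and 3")
})

test_that("diagnostic statistics match the published values", {
  st <- diagnostic_stats(list(tp = 22, fp = 1, fn = 28, tn = 24))
  expect_equal(st$sensitivity, 0.44)
  expect_equal(st$specificity, 0.96)
  expect_equal(st$lr_positive, 11.0)
  expect_equal(st$lr_negative, 0.58333333333, tolerance = 1e-9)
  expect_equal(st$ppv, 22 / 23)
  # at the >=1 rule, sensitivity is 0.88 (specificity computes to 0.40
  # from these counts)
  st1 <- diagnostic_stats(build_contingency(published_counts(), k = 1))
  expect_equal(st1$sensitivity, 0.88)
  expect_equal(st1$specificity, 0.40)
})

test_that("degenerate contingency tables are guarded", {
  perfect <- diagnostic_stats(list(tp = 10, fp = 0, fn = 0, tn = 10))
  expect_equal(perfect$sensitivity, 1)
  expect_true(is.infinite(perfect$lr_positive))
  expect_error(diagnostic_stats(list(tp = 0, fp = 5, fn = 0, tn = 5)),
               "improved")
  expect_error(diagnostic_stats(list(tp = 5, fp = 0, fn = 5, tn = 0)),
               "non-improved")
})

test_that("per-category improvement probabilities match the published ones", {
  ppv <- ppv_per_category(published_counts())
  expect_equal(ppv$ppv_pct[ppv$category == "2-3"], 100 * 22 / 23)
  expect_equal(ppv$ppv_pct[ppv$category == "1"], 100 * 22 / 36)
  expect_equal(ppv$ppv_pct[ppv$category == "0"], 37.5)
  zero <- data.frame(criteria_met = 0:3, n_improved = c(0, 0, 0, 0),
                     n_total = c(10, 5, 0, 0))
  expect_warning(p0 <- ppv_per_category(zero), "empty")
  expect_equal(p0$ppv[p0$category == "0"], 0)
  expect_false("2-3" %in% p0$category)
})

test_that("pooled PPV is the count-weighted average of per-category PPVs", {
  counts <- published_counts()
  st <- diagnostic_stats(build_contingency(counts, 2))
  upper <- counts[counts$criteria_met >= 2, ]
  expect_equal(st$ppv,
               sum(upper$n_total / sum(upper$n_total) *
                     (upper$n_improved / upper$n_total)))
})

test_that("likelihood-ratio identity holds exactly on random tables", {
  set.seed(12)
  for (rep in 1:100) {
    ct <- list(tp = sample(0:30, 1), fp = sample(1:30, 1),
               fn = sample(1:30, 1), tn = sample(0:30, 1))
    st <- diagnostic_stats(ct)
    if (is.finite(st$lr_positive))
      expect_equal(st$lr_positive * (1 - st$specificity), st$sensitivity,
                   tolerance = 1e-12)
    if (is.finite(st$lr_negative) && st$specificity > 0)
      expect_equal(st$lr_negative * st$specificity, 1 - st$sensitivity,
                   tolerance = 1e-12)
  }
})

test_that("ROC sweep passes through the published operating point", {
  roc <- roc_over_k(published_counts())
  expect_equal(roc$fpr[roc$k == 2 & !is.na(roc$k)], 0.04)
  expect_equal(roc$tpr[roc$k == 2 & !is.na(roc$k)], 0.44)
  expect_equal(roc[roc$k == 0 & !is.na(roc$k), c("fpr", "tpr")],
               data.frame(fpr = 1, tpr = 1), ignore_attr = TRUE)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[1], 0)
})

test_that("ROC points are monotone as the count threshold relaxes", {
  set.seed(5)
  for (rep in 1:25) {
    n_tot <- sample(2:20, 4, replace = TRUE)
    n_imp <- vapply(n_tot, function(n) sample(0:n, 1), numeric(1))
    counts <- data.frame(criteria_met = 0:3, n_improved = n_imp,
                         n_total = n_tot)
    if (sum(n_imp) == 0 || sum(n_tot - n_imp) == 0) next
    roc <- roc_over_k(counts)
    expect_true(all(diff(roc$fpr) >= -1e-12))
    expect_true(all(diff(roc$tpr) >= -1e-12))
  }
})

test_that("ANOVA F matches an independent sum-of-squares recomputation", {
  set.seed(9)
  groups <- list(a = rnorm(10, -0.7, 0.5), b = rnorm(10, -0.1, 0.4),
                 c = rnorm(10, 0.0, 0.4))
  av <- one_way_anova(groups)
  expect_equal(av$f, oracle_anova_f(groups), tolerance = 1e-10)
  expect_equal(av$df_between, 2)
  expect_equal(av$df_within, 27)
  expect_equal(av$p, stats::pf(av$f, 2, 27, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("ANOVA F is invariant to a constant shift of every observation", {
  set.seed(10)
  groups <- list(a = rnorm(8), b = rnorm(12, 0.5), c = rnorm(6, -0.3))
  shifted <- lapply(groups, function(g) g + 37.2)
  expect_equal(one_way_anova(groups)$f, one_way_anova(shifted)$f,
               tolerance = 1e-9)
})

test_that("degenerate ANOVA inputs are guarded", {
  expect_error(one_way_anova(list(a = rep(1, 4), b = rep(1, 4))),
               "zero within-group variance")
  expect_error(one_way_anova(list(a = 1:5)), "at least 2 groups")
  expect_error(one_way_anova(list(a = 1:5, b = 2)), "fewer than 2")
  jitter <- list(a = c(0, 0, 0, 0) + c(0, 1e-9, 0, -1e-9),
                 b = c(1, 1, 1, 1) + c(1e-9, 0, -1e-9, 0))
  expect_lt(one_way_anova(jitter)$p, 1e-6)
})

test_that("two-group LSD is exactly the pooled-variance t-test", {
  set.seed(14)
  a <- rnorm(12, -0.7, 0.5)
  b <- rnorm(9, -0.1, 0.4)
  lsd <- lsd_pairwise(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(lsd$p, tt$p.value, tolerance = 1e-12)
  expect_equal(lsd$mean_difference, unname(diff(rev(tt$estimate))),
               tolerance = 1e-12)
  expect_equal(c(lsd$ci_low, lsd$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical groups give a zero contrast with p = 1", {
  g <- c(0.1, -0.2, 0.4, -0.3)
  lsd <- lsd_pairwise(list(a = g, b = g))
  expect_equal(lsd$mean_difference, 0)
  expect_equal(lsd$p, 1)
  expect_equal(lsd$ci_low, -lsd$ci_high)
})

test_that("LSD excludes undersized groups with a warning", {
  set.seed(3)
  groups <- list(a = rnorm(6), b = rnorm(6), tiny = 1)
  expect_warning(lsd <- lsd_pairwise(groups), "tiny")
  expect_equal(nrow(lsd), 1L)
})

test_that("Hedges' g matches its closed form and magnitude bands", {
  same <- hedges_g(10, 0.5, 0.2, 10, 0.5, 0.3)
  expect_equal(same$g, 0)
  expect_equal(same$magnitude, "negligible")

  es <- hedges_g(20, 1, 1, 20, 0, 1)
  expect_equal(es$g, (1 - 3 / 151) * 1, tolerance = 1e-12)
  expect_equal(es$magnitude, "large")

  expect_equal(heatadapt:::.magnitude_label(0.19), "negligible")
  expect_equal(heatadapt:::.magnitude_label(0.2), "small")
  expect_equal(heatadapt:::.magnitude_label(-0.49), "small")
  expect_equal(heatadapt:::.magnitude_label(0.5), "medium")
  expect_equal(heatadapt:::.magnitude_label(0.79), "medium")
  expect_equal(heatadapt:::.magnitude_label(-0.8), "large")

  expect_error(hedges_g(5, 1, 0, 5, 0, 0), "pooled SD")
  expect_error(hedges_g(1, 1, 1, 5, 0, 1), "n >= 2")
  # sign of g follows the sign of the mean difference
  expect_lt(hedges_g(10, -0.7, 0.5, 10, -0.1, 0.4)$g, 0)
})
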