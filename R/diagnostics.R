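# Evaluation layer: per-category improvement probabilities (PPV),
# 2x2-derived sensitivity/specificity and likelihood ratios, the ROC sweep
# over count thresholds, one-way ANOVA with Fisher's LSD contrasts, and
# Hedges' g effect sizes.

#' Tabulate improvement by number of criteria met
#'
#' @param classified Result of [count_criteria()] including the `improved`
#'   column.
#' @return Data frame with one row per criteria count 0..3:
#'   `criteria_met`, `n_improved`, `n_total`.
#' @export
category_counts <- function(classified) {
  if (is.null(classified$improved))
    stop("`classified` must carry the `improved` label", call. = FALSE)
  cats <- 0:3
  data.frame(
    criteria_met = cats,
    n_improved = vapply(cats, function(c)
      sum(classified$improved[classified$criteria_met == c]), numeric(1)),
    n_total = vapply(cats, function(c)
      sum(classified$criteria_met == c), numeric(1)))
}

#' Build the 2x2 contingency table at a count threshold
#'
#' Positive means "at least `k` criteria met"; truth is the improvement
#' label.
#'
#' @param counts Category-count table from [category_counts()].
#' @param k Count threshold, integer in 0..3.
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
build_contingency <- function(counts, k) {
  k <- .check_k(k)
  pos <- counts$criteria_met >= k
  tp <- sum(counts$n_improved[pos])
  fp <- sum(counts$n_total[pos] - counts$n_improved[pos])
  fn <- sum(counts$n_improved[!pos])
  tn <- sum(counts$n_total[!pos] - counts$n_improved[!pos])
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Diagnostic statistics of a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, positive likelihood
#' ratio `sens/(1-spec)` (reported as `Inf` when specificity is 1, so ROC
#' sweeps do not abort), negative likelihood ratio `(1-sens)/spec`, and
#' positive predictive value `tp/(tp+fp)` (`NA` when nothing is predicted
#' positive).
#'
#' @param table Contingency list from [build_contingency()].
#' @return List: `sensitivity`, `specificity`, `lr_positive`,
#'   `lr_negative`, `ppv`.
#' @export
diagnostic_stats <- function(table) {
  with(table, {
    if (tp + fn == 0)
      stop("no truly improved observations; sensitivity undefined",
           call. = FALSE)
    if (fp + tn == 0)
      stop("no truly non-improved observations; specificity undefined",
           call. = FALSE)
    sens <- tp / (tp + fn)
    spec <- tn / (fp + tn)
    list(sensitivity = sens,
         specificity = spec,
         lr_positive = if (spec == 1) Inf else sens / (1 - spec),
         lr_negative = if (spec == 0) Inf else (1 - sens) / spec,
         ppv = if (tp + fp == 0) NA_real_ else tp / (tp + fp))
  })
}

#' Improvement probability per criteria-count category
#'
#' Reports the observed probability of a true rectal-temperature
#' improvement within each criteria-count category, collapsing counts 2
#' and 3 into one "2-3" category as in the published contingency summary.
#' Empty categories are omitted with a warning.
#'
#' @param counts Category-count table from [category_counts()].
#' @return Data frame: `category` (`"0"`, `"1"`, `"2-3"`), `n_improved`,
#'   `n_total`, `ppv` (proportion), `ppv_pct` (percentage).
#' @export
ppv_per_category <- function(counts) {
  groups <- list("0" = 0, "1" = 1, "2-3" = c(2, 3))
  rows <- lapply(names(groups), function(g) {
    sel <- counts$criteria_met %in% groups[[g]]
    n_imp <- sum(counts$n_improved[sel])
    n_tot <- sum(counts$n_total[sel])
    if (n_tot == 0) {
      warning("category ", g, " is empty; omitted", call. = FALSE)
      return(NULL)
    }
    data.frame(category = g, n_improved = n_imp, n_total = n_tot,
               ppv = n_imp / n_tot, ppv_pct = 100 * n_imp / n_tot,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' ROC points over the count threshold
#'
#' Sweeps the count threshold k = 3, 2, 1, 0 and reports
#' `(1 - specificity, sensitivity)` for each, plus the trivial `(0, 0)`
#' endpoint (predict nothing positive). Points are monotone non-decreasing
#' in both coordinates as k decreases.
#'
#' @param counts Category-count table from [category_counts()].
#' @return Data frame: `k` (`NA` for the endpoint), `fpr`, `tpr`.
#' @export
roc_over_k <- function(counts) {
  rows <- lapply(3:0, function(k) {
    st <- diagnostic_stats(build_contingency(counts, k))
    data.frame(k = k, fpr = 1 - st$specificity, tpr = st$sensitivity)
  })
  rbind(data.frame(k = NA_integer_, fpr = 0, tpr = 0), do.call(rbind, rows))
}

.group_stats <- function(groups) {
  data.frame(group = names(groups),
             n = vapply(groups, length, numeric(1)),
             mean = vapply(groups, mean, numeric(1)),
             sd = vapply(groups, stats::sd, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-way ANOVA across criteria-count categories
#'
#' Classical fixed-effects one-way analysis of variance of the
#' rectal-temperature deltas across categories, with (g - 1, N - g)
#' degrees of freedom.
#'
#' @param groups Named list of numeric vectors, one per category; every
#'   group needs at least 2 values.
#' @return List: `f`, `p`, `df_between`, `df_within`, `mse`,
#'   `group_stats` (n/mean/sd per group).
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  small <- vapply(groups, length, numeric(1)) < 2
  if (any(small))
    stop("group(s) with fewer than 2 values: ",
         paste(names(groups)[small], collapse = ", "), call. = FALSE)
  if (all(vapply(groups, stats::var, numeric(1)) == 0))
    stop("zero within-group variance everywhere; F undefined", call. = FALSE)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, numeric(1)))))
  fit <- stats::aov(value ~ group, data = dat)
  tab <- summary(fit)[[1]]
  list(f = tab[["F value"]][1],
       p = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       mse = tab[["Mean Sq"]][2],
       group_stats = .group_stats(groups))
}

#' Fisher's LSD pairwise contrasts
#'
#' Unadjusted pairwise t contrasts using the ANOVA pooled error term:
#' `t = (m_a - m_b) / sqrt(MSE (1/n_a + 1/n_b))` on N - g degrees of
#' freedom, with the confidence interval built from the same standard
#' error, and no multiplicity adjustment. Each contrast also carries
#' Hedges' g and its magnitude label. Groups with fewer than 2 values are
#' excluded with a warning.
#'
#' @param groups Named list of numeric vectors, one per category.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return Data frame: `pair`, `mean_difference`, `ci_low`, `ci_high`,
#'   `t`, `p`, `hedges_g`, `magnitude`.
#' @export
lsd_pairwise <- function(groups, conf_level = 0.95) {
  small <- vapply(groups, length, numeric(1)) < 2
  if (any(small)) {
    warning("excluding group(s) with fewer than 2 values: ",
            paste(names(groups)[small], collapse = ", "), call. = FALSE)
    groups <- groups[!small]
  }
  av <- one_way_anova(groups)
  nms <- names(groups)
  rows <- list()
  for (i in seq_along(nms)[-length(nms)]) {
    for (j in seq((i + 1), length(nms))) {
      a <- groups[[i]]; b <- groups[[j]]
      diff <- mean(a) - mean(b)
      se <- sqrt(av$mse * (1 / length(a) + 1 / length(b)))
      tval <- diff / se
      crit <- stats::qt(1 - (1 - conf_level) / 2, av$df_within)
      es <- hedges_g(length(a), mean(a), stats::sd(a),
                     length(b), mean(b), stats::sd(b))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(nms[i], "vs", nms[j]),
        mean_difference = diff,
        ci_low = diff - crit * se,
        ci_high = diff + crit * se,
        t = tval,
        p = 2 * stats::pt(-abs(tval), av$df_within),
        hedges_g = es$g,
        magnitude = es$magnitude,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.magnitude_label <- function(g) {
  a <- abs(g)
  if (a < 0.2) "negligible"
  else if (a < 0.5) "small"
  else if (a < 0.8) "medium"
  else "large"
}

#' Hedges' g standardized mean difference
#'
#' `g = J (mean_a - mean_b) / s_p` with pooled SD
#' `s_p = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))` and the
#' small-sample correction `J = 1 - 3 / (4 df - 1)`, `df = n_a + n_b - 2`.
#' Magnitude labels follow the conventional bands, closed into half-open
#' intervals: below 0.2 negligible, `[0.2, 0.5)` small, `[0.5, 0.8)`
#' medium, at least 0.8 large.
#'
#' @param n_a,n_b Group sizes (each at least 2).
#' @param mean_a,mean_b Group means.
#' @param sd_a,sd_b Group SDs (non-negative, not both zero).
#' @return List: `g`, `magnitude`.
#' @export
hedges_g <- function(n_a, mean_a, sd_a, n_b, mean_b, sd_b) {
  if (n_a < 2 || n_b < 2)
    stop("both groups need n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0)
    stop("SDs must be non-negative", call. = FALSE)
  df <- n_a + n_b - 2
  s_p <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  if (s_p == 0)
    stop("pooled SD is zero; effect size undefined", call. = FALSE)
  j <- 1 - 3 / (4 * df - 1)
  g <- j * (mean_a - mean_b) / s_p
  list(g = g, magnitude = .magnitude_label(g))
}

#' Full diagnostics report for a classified observation set
#'
#' Assembles the whole evaluation layer: category counts, per-category
#' improvement probabilities, the 2x2 table and its statistics at the
#' configured count threshold, the ROC sweep, one-way ANOVA of the
#' rectal-temperature deltas across categories 0 / 1 / 2-3, and LSD
#' pairwise contrasts with Hedges' g.
#'
#' @param classified Result of [count_criteria()] carrying `improved` and
#'   `d_trec`.
#' @param k Count threshold (default: the one recorded by
#'   [count_criteria()], else 2).
#' @param conf_level Confidence level for LSD intervals.
#' @return Object of class `diagnostics_report`; print it for a plain-text
#'   summary including the Venn-style breakdown by rule pattern.
#' @export
diagnostics_report <- function(classified, k = attr(classified, "k") %||% 2,
                               conf_level = 0.95) {
  k <- .check_k(k)
  counts <- category_counts(classified)
  ct <- build_contingency(counts, k)
  stats_k <- diagnostic_stats(ct)
  cat_label <- ifelse(classified$criteria_met >= 2, "2-3",
                      as.character(classified$criteria_met))
  groups <- split(classified$d_trec, cat_label)
  groups <- groups[order(match(names(groups), c("2-3", "1", "0")))]
  usable <- vapply(groups, length, numeric(1)) >= 2
  anova <- if (sum(usable) >= 2) one_way_anova(groups[usable]) else NULL
  pairwise <- if (sum(usable) >= 2)
    suppressWarnings(lsd_pairwise(groups, conf_level)) else NULL

  venn <- stats::aggregate(
    cbind(n = rep(1, nrow(classified)),
          n_improved = as.numeric(classified$improved)),
    by = list(hr_met = classified$hr_met, sr_met = classified$sr_met,
              ts_met = classified$ts_met),
    FUN = sum)

  structure(list(k = k,
                 category_counts = counts,
                 ppv = ppv_per_category(counts),
                 contingency = ct,
                 sensitivity = stats_k$sensitivity,
                 specificity = stats_k$specificity,
                 lr_positive = stats_k$lr_positive,
                 lr_negative = stats_k$lr_negative,
                 ppv_at_k = stats_k$ppv,
                 roc = roc_over_k(counts),
                 anova = anova,
                 pairwise = pairwise,
                 venn = venn),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Rectal-temperature adaptation diagnostics (k =", x$k, ")\n\n")
  cat("Improvement probability by number of criteria met:\n")
  for (i in seq_len(nrow(x$ppv))) {
    r <- x$ppv[i, ]
    cat(sprintf("  %3s criteria: %d / %d improved (%.1f%%)\n",
                r$category, r$n_improved, r$n_total, r$ppv_pct))
  }
  cat(sprintf("\nAt >= %d criteria: sensitivity %.2f, specificity %.2f, LR+ %s, LR- %.2f\n",
              x$k, x$sensitivity, x$specificity,
              if (is.infinite(x$lr_positive)) "Inf" else
                sprintf("%.1f", x$lr_positive),
              x$lr_negative))
  cat("\nVenn breakdown (HR / SR / TS rule pattern -> improved / n):\n")
  for (i in seq_len(nrow(x$venn))) {
    v <- x$venn[i, ]
    pat <- paste(ifelse(c(v$hr_met, v$sr_met, v$ts_met),
                        c("HR", "SR", "TS"), "--"), collapse = " ")
    cat(sprintf("  [%s] %d / %d\n", pat, v$n_improved, v$n))
  }
  if (!is.null(x$anova))
    cat(sprintf("\nANOVA of d_trec across categories: F(%d, %d) = %.2f, p = %.4g\n",
                x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise (LSD) contrasts of d_trec:\n")
    for (i in seq_len(nrow(x$pairwise))) {
      pw <- x$pairwise[i, ]
      cat(sprintf("  %-10s %+0.2f degC [%+.2f, %+.2f], g = %.2f (%s), p = %.4g\n",
                  pw$pair, pw$mean_difference, pw$ci_low, pw$ci_high,
                  pw$hedges_g, pw$magnitude, pw$p))
    }
  }
  invisible(x)
}
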