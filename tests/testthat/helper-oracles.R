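# Independent brute-force oracles, written with plain loops so they share
# no code path with the package implementation.

# Entropy of a label vector, directly from the definition.
oracle_entropy <- function(labels) {
  n <- length(labels)
  if (n == 0) return(0)
  p <- sum(labels) / n
  h <- 0
  for (q in c(p, 1 - p)) if (q > 0) h <- h - q * log2(q)
  h
}

# Exhaustive single-split scan at midpoint thresholds, replicating the
# selection policy by explicit enumeration. Returns the chosen threshold.
oracle_best_threshold <- function(x, labels, favorable_side, strict,
                                  policy = "max_ppv_min_support",
                                  min_support_fraction = 0.25) {
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("oracle: fewer than 2 distinct values")
  thresholds <- numeric(0)
  for (i in seq_len(length(ux) - 1))
    thresholds <- c(thresholds, (ux[i] + ux[i + 1]) / 2)

  n <- length(x)
  best <- NULL
  for (t in thresholds) {
    fav <- logical(n)
    for (i in seq_len(n)) {
      fav[i] <- if (favorable_side == "below") {
        if (strict) x[i] < t else x[i] <= t
      } else {
        if (strict) x[i] > t else x[i] >= t
      }
    }
    n_fav <- sum(fav)
    p_fav <- if (n_fav > 0) sum(labels[fav]) / n_fav else NA
    child <- (n_fav / n) * oracle_entropy(labels[fav]) +
      ((n - n_fav) / n) * oracle_entropy(labels[!fav])
    gain <- max(oracle_entropy(labels) - child, 0)
    cand <- list(t = t, n_fav = n_fav, p = p_fav, gain = gain)

    ok <- if (policy == "max_ppv_min_support") {
      !is.na(p_fav) && n_fav >= ceiling(min_support_fraction * n)
    } else TRUE
    if (!ok) next
    score <- if (policy == "max_ppv_min_support") cand$p else cand$gain
    if (is.null(best) ||
        score > best$score ||
        (score == best$score && cand$n_fav > best$n_fav) ||
        (score == best$score && cand$n_fav == best$n_fav &&
         abs(cand$t) < abs(best$t))) {
      best <- cand
      best$score <- score
    }
  }
  if (is.null(best)) stop("oracle: no candidate meets the support floor")
  best$t
}

# Textbook sum-of-squares decomposition for one-way ANOVA.
oracle_anova_f <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  g <- length(groups)
  n <- length(all_vals)
  (ssb / (g - 1)) / (ssw / (n - g))
}

# Minimal observation table for split tests.
obs_table <- function(values, labels, variable = "d_hr") {
  df <- data.frame(participant_id = sprintf("P%03d", seq_along(values)),
                   induction = "HAz",
                   d_hr = 0, d_sr = 0, d_ts = 0,
                   d_trec = ifelse(labels, -1, 1),
                   improved = labels,
                   stringsAsFactors = FALSE)
  df[[variable]] <- values
  df
}
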