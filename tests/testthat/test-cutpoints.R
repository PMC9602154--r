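# Entropy split scan and cut-point selection policy.

test_that("binary entropy matches the closed form", {
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0.25), 0.811278124459133, tolerance = 1e-12)
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
  expect_error(binary_entropy(1.1), "\\[0, 1\\]")
})

test_that("a clean separating split earns the full bit of information", {
  obs <- obs_table(c(-20, -15, -14, -5, -2, 0), c(TRUE, TRUE, TRUE,
                                                  FALSE, FALSE, FALSE))
  s <- evaluate_split(obs, "d_hr", -13, "below", strict = TRUE)
  expect_equal(s$n_favorable, 3)
  expect_equal(s$n_total, 6)
  expect_equal(s$p_improved, 1)
  expect_equal(s$parent_entropy, 1)
  expect_equal(s$child_entropy, 0)
  expect_equal(s$info_gain, 1)
})

test_that("a label-balanced split gains nothing", {
  obs <- obs_table(1:4, c(TRUE, FALSE, TRUE, FALSE))
  s <- evaluate_split(obs, "d_hr", 2.5, "below", strict = TRUE)
  expect_equal(s$n_favorable, 2)
  expect_equal(s$p_improved, 0.5)
  expect_equal(s$info_gain, 0)
})

test_that("constant labels give zero parent entropy and zero gain everywhere", {
  obs <- obs_table(c(-8, -4, -1, 3), rep(TRUE, 4))
  cands <- enumerate_candidates(obs, "d_hr")
  expect_true(all(cands$parent_entropy == 0))
  expect_true(all(cands$info_gain == 0))
})

test_that("candidate thresholds are midpoints or a snapped regular grid", {
  obs <- obs_table(c(1, 2, 3, 2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(enumerate_candidates(obs, "d_hr")$threshold, c(1.5, 2.5))

  obs6 <- obs_table(c(-20, -15, -14, -5, -2, 0), rep(c(TRUE, FALSE), each = 3))
  expect_equal(nrow(enumerate_candidates(obs6, "d_hr")), 5L)
  grid <- enumerate_candidates(obs6, "d_hr", grid_step = 1)
  expect_equal(grid$threshold, seq(-20, 0, by = 1))
  expect_equal(nrow(grid), 21L)

  one <- obs_table(c(2, 2, 2), c(TRUE, FALSE, TRUE))
  expect_equal(nrow(enumerate_candidates(one, "d_hr")), 0L)
})

test_that("an empty split side is void: gain zero, favorable p missing", {
  obs <- obs_table(c(-20, -15, -14, -5), c(TRUE, TRUE, FALSE, FALSE))
  s <- evaluate_split(obs, "d_hr", -30, "below", strict = TRUE)
  expect_equal(s$n_favorable, 0)
  expect_true(is.na(s$p_improved))
  expect_equal(s$info_gain, 0)
  expect_equal(s$child_entropy, s$parent_entropy)
})

test_that("selection balances probability against support as published", {
  # the published worked comparison: 78% with 41 cases vs 82% with 22 cases,
  # support floor ceiling(0.25 * 75) = 19 -> the 82%/22-case split wins
  cands <- data.frame(
    variable = "d_hr", threshold = c(-5, -13),
    n_favorable = c(41, 22), n_total = 75,
    p_improved = c(0.78, 0.82),
    parent_entropy = 1, child_entropy = 0.9, info_gain = 0.1,
    stringsAsFactors = FALSE)
  attr(cands, "favorable_side") <- "below"
  attr(cands, "strict") <- TRUE
  sel <- select_cutpoint(cands, "max_ppv_min_support", 0.25)
  expect_equal(sel$rule$threshold, -13)
  expect_s3_class(sel$rule, "cutpoint_rule")
  expect_identical(sel$candidates, cands)

  # single qualifying candidate
  expect_equal(select_cutpoint(cands[1, ], "max_ppv_min_support")$rule$threshold,
               -5)
  # ties in p and support break toward the threshold nearest zero
  tie <- cands
  tie$threshold <- c(-17, -13)
  tie$p_improved <- 0.8
  tie$n_favorable <- 22
  expect_equal(select_cutpoint(tie)$rule$threshold, -13)
  # an unreachable support floor is a clear error
  expect_error(select_cutpoint(cands, min_support_fraction = 0.9),
               "min_support_fraction")
})

test_that("selected cut-point matches exhaustive brute force on small sets", {
  set.seed(2024)
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    x <- round(rnorm(n, 0, 8))
    y <- runif(n) < 0.5
    if (length(unique(x)) < 2 || !any(y) || all(y)) next
    side <- sample(c("below", "above"), 1)
    for (policy in c("max_ppv_min_support", "max_info_gain")) {
      obs <- obs_table(x, y)
      got <- tryCatch(
        search_cutpoint(obs, "d_hr", favorable_side = side, strict = TRUE,
                        policy = policy,
                        min_support_fraction = 0.25)$rule$threshold,
        error = function(e) NA_real_)
      want <- tryCatch(
        oracle_best_threshold(x, y, side, TRUE, policy, 0.25),
        error = function(e) NA_real_)
      expect_equal(got, want,
                   info = sprintf("rep %d policy %s side %s", rep, policy, side))
    }
  }
})

test_that("candidate statistics are invariant to observation order", {
  set.seed(7)
  obs <- obs_table(rnorm(30), runif(30) < 0.4)
  shuffled <- obs[sample(nrow(obs)), ]
  a <- enumerate_candidates(obs, "d_hr")
  b <- enumerate_candidates(shuffled, "d_hr")
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  expect_identical(search_cutpoint(obs, "d_hr")$rule,
                   search_cutpoint(shuffled, "d_hr")$rule)
})

test_that("information gain is bounded by the parent entropy", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    obs <- obs_table(rnorm(n), runif(n) < runif(1))
    cands <- enumerate_candidates(obs, "d_hr")
    if (!nrow(cands)) next
    expect_true(all(cands$info_gain >= 0))
    expect_true(all(cands$info_gain <= cands$parent_entropy + 1e-12))
    expect_true(all(cands$parent_entropy <= 1))
    expect_true(all(cands$n_favorable <= cands$n_total))
  }
})

test_that("published rules carry the published thresholds and boundary semantics", {
  rules <- published_rules()
  expect_equal(unclass(rules$d_hr),
               list(variable = "d_hr", threshold = -13,
                    favorable_side = "below", strict = TRUE))
  expect_equal(unclass(rules$d_sr),
               list(variable = "d_sr", threshold = 0.3,
                    favorable_side = "above", strict = TRUE))
  expect_equal(unclass(rules$d_ts),
               list(variable = "d_ts", threshold = -0.5,
                    favorable_side = "below", strict = FALSE))
})
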