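# Single-split, entropy-minimizing cut-point scan per predictor delta, and
# the selection policy trading improvement probability against support.

.CUT_VARS <- c("d_hr", "d_sr", "d_ts")

# Favorable direction is fixed a priori by the sign convention: improvement
# is heart rate and thermal sensation falling, sweat rate rising.
.DEFAULT_SIDE <- c(d_hr = "below", d_sr = "above", d_ts = "below")
.DEFAULT_STRICT <- c(d_hr = TRUE, d_sr = TRUE, d_ts = FALSE)

#' A cut-point rule on one adaptation delta
#'
#' A rule is met when the delta lies on `favorable_side` of `threshold`;
#' `strict` controls whether a delta exactly at the threshold counts.
#'
#' @param variable One of `"d_hr"`, `"d_sr"`, `"d_ts"`.
#' @param threshold Threshold in the variable's units.
#' @param favorable_side `"below"` or `"above"`; defaults to the
#'   sign-convention side for the variable.
#' @param strict Logical; `TRUE` for a strict inequality at the boundary.
#' @return An object of class `cutpoint_rule`.
#' @export
cutpoint_rule <- function(variable, threshold,
                          favorable_side = .DEFAULT_SIDE[[variable]],
                          strict = .DEFAULT_STRICT[[variable]]) {
  variable <- match.arg(variable, .CUT_VARS)
  favorable_side <- match.arg(favorable_side, c("below", "above"))
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("`threshold` must be a single finite number", call. = FALSE)
  structure(list(variable = variable, threshold = threshold,
                 favorable_side = favorable_side, strict = isTRUE(strict)),
            class = "cutpoint_rule")
}

#' @export
print.cutpoint_rule <- function(x, ...) {
  op <- if (x$favorable_side == "below") {
    if (x$strict) "<" else "<="
  } else {
    if (x$strict) ">" else ">="
  }
  cat(sprintf("cut-point rule: %s %s %g\n", x$variable, op, x$threshold))
  invisible(x)
}

#' The published cut-point rules
#'
#' Heart-rate delta below -13 bpm (strict), sweat-rate delta above
#' 0.3 L/h (strict), thermal-sensation delta at or below -0.5 (non-strict).
#'
#' @return Named list of three [cutpoint_rule()] objects.
#' @export
published_rules <- function() {
  list(d_hr = cutpoint_rule("d_hr", -13, "below", strict = TRUE),
       d_sr = cutpoint_rule("d_sr", 0.3, "above", strict = TRUE),
       d_ts = cutpoint_rule("d_ts", -0.5, "below", strict = FALSE))
}

rule_met <- function(rule, x) {
  if (rule$favorable_side == "below") {
    if (rule$strict) x < rule$threshold else x <= rule$threshold
  } else {
    if (rule$strict) x > rule$threshold else x >= rule$threshold
  }
}

#' Shannon entropy of a binary outcome
#'
#' `-p log2 p - (1 - p) log2 (1 - p)` in bits, with `0 log2 0 = 0`.
#'
#' @param p Proportion(s) in `[0, 1]`.
#' @return Entropy in bits, in `[0, 1]`.
#' @export
binary_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Evaluate one candidate split of the improvement labels
#'
#' Partitions the observations at `threshold` on `variable`, reports the
#' improvement probability and support on the favorable side, and the
#' entropy bookkeeping of the split: parent entropy, child entropy weighted
#' by side size, and information gain. If one side is empty the split is
#' void and the gain is 0.
#'
#' @param observations Delta data frame with an `improved` column (see
#'   [compute_deltas()]).
#' @param variable,threshold,favorable_side,strict Rule components as in
#'   [cutpoint_rule()].
#' @return One-row data frame: `variable`, `threshold`, `n_favorable`,
#'   `n_total`, `p_improved` (`NA` when the favorable side is empty),
#'   `parent_entropy`, `child_entropy`, `info_gain` (bits).
#' @export
evaluate_split <- function(observations, variable, threshold,
                           favorable_side = .DEFAULT_SIDE[[variable]],
                           strict = .DEFAULT_STRICT[[variable]]) {
  variable <- match.arg(variable, .CUT_VARS)
  x <- observations[[variable]]
  y <- observations$improved
  if (length(x) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite values of `", variable, "`", call. = FALSE)
  rule <- cutpoint_rule(variable, threshold, favorable_side, strict)
  fav <- rule_met(rule, x)
  n <- length(x)
  n_fav <- sum(fav)
  parent <- binary_entropy(mean(y))
  child <- 0
  for (side in list(y[fav], y[!fav])) {
    if (length(side))
      child <- child + (length(side) / n) * binary_entropy(mean(side))
  }
  data.frame(variable = variable, threshold = threshold,
             n_favorable = n_fav, n_total = n,
             p_improved = if (n_fav) mean(y[fav]) else NA_real_,
             parent_entropy = parent, child_entropy = child,
             info_gain = max(parent - child, 0),
             stringsAsFactors = FALSE)
}

#' Enumerate and evaluate candidate thresholds for one variable
#'
#' With `grid_step` unset, candidate thresholds are the midpoints between
#' consecutive distinct sorted values of the variable (every distinct
#' binary partition, each threshold midway for stability). With `grid_step`
#' set, candidates form a regular grid of multiples of the step spanning
#' the observed range, matching how a practitioner would scan at the
#' instrument resolution.
#'
#' @inheritParams evaluate_split
#' @param grid_step Optional positive grid spacing in the variable's units.
#' @return Data frame of evaluated candidates, ordered by threshold, with
#'   attributes `favorable_side` and `strict`. Zero rows when fewer than
#'   two distinct values exist.
#' @export
enumerate_candidates <- function(observations, variable,
                                 favorable_side = .DEFAULT_SIDE[[variable]],
                                 strict = .DEFAULT_STRICT[[variable]],
                                 grid_step = NULL) {
  variable <- match.arg(variable, .CUT_VARS)
  x <- observations[[variable]]
  if (any(!is.finite(x)))
    stop("non-finite values of `", variable, "`", call. = FALSE)
  ux <- sort(unique(x))
  thresholds <- if (is.null(grid_step)) {
    if (length(ux) < 2L) numeric(0) else (ux[-1] + ux[-length(ux)]) / 2
  } else {
    if (length(grid_step) != 1L || !is.finite(grid_step) || grid_step <= 0)
      stop("`grid_step` must be a single positive number", call. = FALSE)
    if (length(ux) < 2L) numeric(0) else
      seq(ceiling(min(ux) / grid_step), floor(max(ux) / grid_step)) * grid_step
  }
  rows <- lapply(thresholds, function(t)
    evaluate_split(observations, variable, t, favorable_side, strict))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), threshold = numeric(),
               n_favorable = integer(), n_total = integer(),
               p_improved = numeric(), parent_entropy = numeric(),
               child_entropy = numeric(), info_gain = numeric(),
               stringsAsFactors = FALSE)
  attr(out, "favorable_side") <- favorable_side
  attr(out, "strict") <- isTRUE(strict)
  out
}

#' Select a cut-point from an evaluated candidate table
#'
#' The default policy `"max_ppv_min_support"` makes the probability/support
#' balance explicit: candidates whose favorable side holds fewer than
#' `ceiling(min_support_fraction * n_total)` observations are discarded,
#' and among the rest the one with the highest favorable-side improvement
#' probability wins. `"max_info_gain"` instead picks the candidate with the
#' largest information gain (the pure entropy-minimizing split). Ties break
#' toward larger favorable support, then toward the threshold nearest zero.
#' The full candidate table is returned alongside the chosen rule so the
#' trade-off can be audited.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param policy `"max_ppv_min_support"` (default) or `"max_info_gain"`.
#' @param min_support_fraction Minimum favorable-side support as a fraction
#'   of the pooled observation count (default 0.25).
#' @return List with elements `rule` (a [cutpoint_rule()]) and `candidates`
#'   (the full table).
#' @export
select_cutpoint <- function(candidates,
                            policy = c("max_ppv_min_support",
                                       "max_info_gain"),
                            min_support_fraction = 0.25) {
  policy <- match.arg(policy)
  if (!nrow(candidates))
    stop("empty candidate list", call. = FALSE)
  pool <- candidates
  if (policy == "max_ppv_min_support") {
    floor_n <- ceiling(min_support_fraction * candidates$n_total[1])
    pool <- candidates[!is.na(candidates$p_improved) &
                         candidates$n_favorable >= floor_n, , drop = FALSE]
    if (!nrow(pool))
      stop("no candidate has favorable support >= ", floor_n,
           "; lower `min_support_fraction`", call. = FALSE)
    score <- pool$p_improved
  } else {
    score <- pool$info_gain
  }
  ord <- order(-score, -pool$n_favorable, abs(pool$threshold))
  best <- pool[ord[1], ]
  rule <- cutpoint_rule(best$variable, best$threshold,
                        attr(candidates, "favorable_side") %||%
                          .DEFAULT_SIDE[[best$variable]],
                        attr(candidates, "strict") %||%
                          .DEFAULT_STRICT[[best$variable]])
  list(rule = rule, candidates = candidates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan one variable and select its cut-point
#'
#' Convenience composition of [enumerate_candidates()] and
#' [select_cutpoint()].
#'
#' @inheritParams enumerate_candidates
#' @inheritParams select_cutpoint
#' @return As [select_cutpoint()].
#' @export
search_cutpoint <- function(observations, variable,
                            favorable_side = .DEFAULT_SIDE[[variable]],
                            strict = .DEFAULT_STRICT[[variable]],
                            policy = "max_ppv_min_support",
                            min_support_fraction = 0.25,
                            grid_step = NULL) {
  cands <- enumerate_candidates(observations, variable, favorable_side,
                                strict, grid_step)
  select_cutpoint(cands, policy, min_support_fraction)
}

#' Export a candidate table
#'
#' Comma-delimited text with header
#' `variable,threshold,n_favorable,n_total,p_improved,parent_entropy,child_entropy,info_gain`.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
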