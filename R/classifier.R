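# Count-of-criteria (Venn) classifier over the three cut-point rules, and
# the univariate logistic regressions on each binary rule indicator.

.CLASS_HEADER <- c("participant_id", "induction", "hr_met", "sr_met",
                   "ts_met", "criteria_met", "predicted_improved")

.check_rules <- function(rules) {
  vars <- vapply(rules, function(r) r$variable, character(1))
  if (!setequal(vars, .CUT_VARS) || length(vars) != 3L)
    stop("`rules` must cover d_hr, d_sr and d_ts exactly once", call. = FALSE)
  stats::setNames(rules, vars)
}

.check_k <- function(k) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 0 || k > 3)
    stop("`k` must be an integer between 0 and 3", call. = FALSE)
  as.integer(k)
}

#' Apply the three cut-point rules and count criteria met
#'
#' Evaluates each observation against the heart-rate, sweat-rate and
#' thermal-sensation cut-point rules (each with its own direction and
#' boundary strictness), counts how many are met, and predicts improvement
#' when the count reaches `k`.
#'
#' @param observations Delta data frame (see [compute_deltas()]).
#' @param rules List of three [cutpoint_rule()] objects covering `d_hr`,
#'   `d_sr`, `d_ts` exactly once; defaults to [published_rules()].
#' @param k Count threshold for predicting improvement, an integer in
#'   0..3 (default 2, i.e. "two or three variables met").
#' @return Data frame with `participant_id`, `induction`, `hr_met`,
#'   `sr_met`, `ts_met`, `criteria_met`, `predicted_improved`; the
#'   `improved` label and `d_trec` are carried through when present so the
#'   result feeds [diagnostics_report()] directly.
#' @examples
#' obs <- make_fixture_observations()
#' cls <- count_criteria(obs)
#' table(cls$criteria_met, cls$improved)
#' @export
count_criteria <- function(observations, rules = published_rules(), k = 2) {
  rules <- .check_rules(rules)
  k <- .check_k(k)
  for (v in .CUT_VARS) {
    if (any(!is.finite(observations[[v]])))
      stop("non-finite values of `", v, "`", call. = FALSE)
  }
  out <- data.frame(
    participant_id = observations$participant_id,
    induction = observations$induction,
    hr_met = rule_met(rules$d_hr, observations$d_hr),
    sr_met = rule_met(rules$d_sr, observations$d_sr),
    ts_met = rule_met(rules$d_ts, observations$d_ts),
    stringsAsFactors = FALSE)
  out$criteria_met <- out$hr_met + out$sr_met + out$ts_met
  out$predicted_improved <- out$criteria_met >= k
  if (!is.null(observations$improved)) out$improved <- observations$improved
  if (!is.null(observations$d_trec)) out$d_trec <- observations$d_trec
  attr(out, "k") <- k
  out
}

#' Export a classification table
#'
#' Comma-delimited text with header
#' `participant_id,induction,hr_met,sr_met,ts_met,criteria_met,predicted_improved`.
#'
#' @param classified Result of [count_criteria()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classified, path) {
  utils::write.csv(classified[, .CLASS_HEADER, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Univariate logistic regression on one cut-point indicator
#'
#' Fits `improved ~ met` by maximum likelihood (iteratively reweighted
#' least squares, gradient tolerance 1e-8, at most 100 iterations), where
#' `met` is the 0/1 indicator of the observation meeting the given rule.
#' Reports the Wald p-value for the slope and both common pseudo-R2
#' variants; which of the two a given statistics package prints varies, so
#' both are returned side by side.
#'
#' Complete separation (a fitted cell probability numerically 0 or 1) is
#' flagged by `converged = FALSE` rather than an error: the slope estimate
#' is unbounded there and its Wald statistic meaningless.
#'
#' @param observations Delta data frame with an `improved` column.
#' @param rule A [cutpoint_rule()].
#' @return List of class `logistic_fit`: `variable`, `intercept`, `slope`,
#'   `wald_p`, `pseudo_r2_cox_snell`, `pseudo_r2_nagelkerke`, `converged`.
#' @export
fit_univariate_logistic <- function(observations, rule) {
  if (!inherits(rule, "cutpoint_rule"))
    stop("`rule` must be a cutpoint_rule", call. = FALSE)
  y <- observations$improved
  if (length(y) < 10L)
    stop("need at least 10 observations", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic fit undefined", call. = FALSE)
  x <- as.numeric(rule_met(rule, observations[[rule$variable]]))

  fit <- suppressWarnings(stats::glm(
    y ~ x, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  n <- length(y)
  eps <- 1e-7
  separated <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  cox_snell <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  nagelkerke <- cox_snell / (1 - exp(-fit$null.deviance / n))
  coefs <- summary(fit)$coefficients
  wald_p <- if ("x" %in% rownames(coefs)) coefs["x", "Pr(>|z|)"] else NA_real_

  structure(list(variable = rule$variable,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)["x"]),
                 wald_p = unname(wald_p),
                 pseudo_r2_cox_snell = cox_snell,
                 pseudo_r2_nagelkerke = nagelkerke,
                 converged = fit$converged && !separated,
                 fitted = fit$fitted.values),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit improved ~ [%s met]: intercept %.4f, slope %.4f, Wald p %.4g\n",
    x$variable, x$intercept, x$slope, x$wald_p))
  cat(sprintf("  pseudo-R2: Cox-Snell %.4f, Nagelkerke %.4f; converged: %s\n",
              x$pseudo_r2_cox_snell, x$pseudo_r2_nagelkerke, x$converged))
  invisible(x)
}
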