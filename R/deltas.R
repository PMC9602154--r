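# Phase records -> per-participant adaptation deltas for the three
# induction contrasts (HAz: post_haz - baseline; HA: post_ha - post_haz;
# DHE: post_ha - baseline) with the binary T_rec improvement label.

.INDUCTIONS <- c("HAz", "HA", "DHE")
.DELTA_HEADER <- c("participant_id", "induction", "d_hr", "d_sr", "d_ts",
                   "d_trec", "improved")

# (pre-phase, post-phase) per contrast
.CONTRASTS <- list(HAz = c("baseline", "post_haz"),
                   HA  = c("post_haz", "post_ha"),
                   DHE = c("baseline", "post_ha"))

#' Label a rectal-temperature delta as improved
#'
#' Improvement means the end-of-trial rectal temperature fell across the
#' induction period: `d_trec < -tolerance`. The default tolerance of 0 degC
#' makes the rule strict negativity; a delta exactly at `-tolerance` is not
#' improved.
#'
#' @param d_trec Numeric vector of rectal-temperature deltas (degC,
#'   post minus pre).
#' @param tolerance Non-negative margin in degC (default 0).
#' @return Logical vector.
#' @export
label_improvement <- function(d_trec, tolerance = 0) {
  if (length(tolerance) != 1L || !is.finite(tolerance) || tolerance < 0)
    stop("`tolerance` must be a single non-negative number", call. = FALSE)
  if (any(!is.finite(d_trec)))
    stop("`d_trec` must be finite", call. = FALSE)
  d_trec < -tolerance
}

# Exact grid differencing: phase values sit on the measurement grid, so
# differences of their integer grid indices make the DHE delta equal the sum
# of the HAz and HA deltas exactly, with no floating-point drift.
.grid_delta <- function(post, pre, step) {
  as.numeric(as.character((round(post / step) - round(pre / step)) * step))
}

#' Compute adaptation deltas for the three induction contrasts
#'
#' For every participant with all three trial phases, produces three delta
#' observations: acclimatization (`HAz`, post-HAz minus baseline),
#' acclimation (`HA`, post-HA minus post-HAz) and the combined dual heat
#' exposure (`DHE`, post-HA minus baseline). Deltas are differenced on the
#' measurement grid of each variable so that, per participant and variable,
#' the DHE delta equals the HAz delta plus the HA delta exactly.
#'
#' @param records Trial data frame (see [generate_cohort()] /
#'   [read_trials()]).
#' @param tolerance Improvement margin in degC passed to
#'   [label_improvement()].
#' @param allow_partial If `FALSE` (default), a participant missing any
#'   phase is an error; if `TRUE`, such participants contribute only the
#'   contrasts whose two phases are present.
#' @param quanta Named measurement resolutions used for exact grid
#'   differencing; defaults to the standard instrument resolutions
#'   (1 bpm, 0.01 degC, 0.5 scale units, 0.01 L/h).
#' @return Data frame with columns `participant_id`, `induction`
#'   (`HAz`/`HA`/`DHE`), `d_hr`, `d_sr`, `d_ts`, `d_trec`, `improved`.
#' @export
compute_deltas <- function(records, tolerance = 0, allow_partial = FALSE,
                           quanta = .default_quanta()) {
  validate_trials(records)
  ids <- unique(records$participant_id)
  key <- function(id, phase) paste(id, phase, sep = "\r")
  row_of <- stats::setNames(seq_len(nrow(records)),
                            key(records$participant_id, records$phase))

  have_all <- vapply(ids, function(id)
    all(key(id, .PHASES) %in% names(row_of)), logical(1))
  if (!allow_partial && any(!have_all))
    stop("participant(s) missing a phase: ",
         paste(ids[!have_all], collapse = ", "),
         " (use allow_partial = TRUE to keep their computable contrasts)",
         call. = FALSE)

  blocks <- lapply(.INDUCTIONS, function(ind) {
    pre <- row_of[key(ids, .CONTRASTS[[ind]][1])]
    post <- row_of[key(ids, .CONTRASTS[[ind]][2])]
    keep <- !is.na(pre) & !is.na(post)
    data.frame(
      participant_id = ids[keep],
      induction = rep(ind, sum(keep)),
      d_hr = .grid_delta(records$hr_peak[post[keep]],
                         records$hr_peak[pre[keep]], quanta[["hr"]]),
      d_sr = .grid_delta(records$sweat_rate[post[keep]],
                         records$sweat_rate[pre[keep]], quanta[["sr"]]),
      d_ts = .grid_delta(records$ts_peak[post[keep]],
                         records$ts_peak[pre[keep]], quanta[["ts"]]),
      d_trec = .grid_delta(records$trec_end[post[keep]],
                           records$trec_end[pre[keep]], quanta[["trec"]]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  # one block per contrast -> reorder to participant-major, contrast-minor
  out <- out[order(match(out$participant_id, ids),
                   match(out$induction, .INDUCTIONS)), , drop = FALSE]
  out$improved <- label_improvement(out$d_trec, tolerance)
  rownames(out) <- NULL
  out
}

validate_deltas <- function(obs) {
  missing_cols <- setdiff(.DELTA_HEADER, names(obs))
  if (length(missing_cols))
    stop("delta table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(obs$induction), .INDUCTIONS)
  if (length(bad))
    stop("unknown induction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  key <- paste(obs$participant_id, obs$induction)
  if (anyDuplicated(key))
    stop("duplicate (participant, induction) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  invisible(obs)
}

#' Write / read a delta-observation table
#'
#' Comma-delimited text with header
#' `participant_id,induction,d_hr,d_sr,d_ts,d_trec,improved`; induction is
#' spelled `HAz`/`HA`/`DHE` and `improved` is `TRUE`/`FALSE`.
#'
#' @param obs Delta data frame as returned by [compute_deltas()].
#' @param path File path.
#' @return `write_deltas()` returns `path` invisibly; `read_deltas()` the
#'   validated data frame.
#' @export
write_deltas <- function(obs, path) {
  validate_deltas(obs)
  utils::write.csv(obs[, .DELTA_HEADER, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_deltas
#' @export
read_deltas <- function(path) {
  if (!file.exists(path))
    stop("delta file does not exist: ", path, call. = FALSE)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(obs), .DELTA_HEADER))
    stop("delta file header must be exactly: ",
         paste(.DELTA_HEADER, collapse = ","), call. = FALSE)
  for (col in c("d_hr", "d_sr", "d_ts", "d_trec")) {
    obs[[col]] <- suppressWarnings(as.numeric(obs[[col]]))
    bad <- which(!is.finite(obs[[col]]))
    if (length(bad))
      stop("non-numeric `", col, "` in row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  obs$improved <- as.logical(obs$improved)
  validate_deltas(obs)
  obs
}
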