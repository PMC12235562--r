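#' Trim behavioral trials
#'
#' Drops fast guesses (`rt <= rt_min_ms`, default 200 ms), timeouts, and
#' slow responses (`rt >= rt_max_ms`, default 1400 ms, matching the epoch
#' criterion so EEG and behavioral analyses cover the same trials).
#' Incorrect trials are retained here: they enter the error rate but are
#' excluded from RT / IES by [compute_dvs()]. The three drop rules commute,
#' so trimming is order-independent.
#'
#' @param tt a trial table.
#' @param cfg an `analysis_config`.
#' @return the trimmed trial table, with attribute `trim` holding per-rule
#'   counts.
#' @export
trim_trials <- function(tt, cfg = analysis_config()) {
  if (!all(c("rt", "accuracy") %in% names(tt)))
    stop("trial table lacks rt/accuracy columns", call. = FALSE)
  fast <- !is.na(tt$rt) & tt$rt <= cfg$rt_min_ms
  slow <- !is.na(tt$rt) & tt$rt >= cfg$rt_max_ms
  timeout <- !is.na(tt$accuracy) & tt$accuracy == "timeout"
  keep <- !(fast | slow | timeout)
  out <- tt[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out))
    message("trim_trials: no trials survive trimming")
  attr(out, "trim") <- c(fast = sum(fast), slow = sum(slow),
                         timeout = sum(timeout), retained = sum(keep))
  out
}

#' Behavioral dependent variables per design cell
#'
#' For each (subject, age group, context, cue type, congruency) cell of a
#' trimmed trial table: mean correct reaction time (RT), error rate
#' `ERR = incorrect / (correct + incorrect)` (timeouts are omissions and
#' never reach this function after trimming), and the inverse efficiency
#' score `IES = mean correct RT / p(correct)`. Cells with no correct trials
#' get `NA` RT and IES with a warning.
#'
#' @param tt a trimmed trial table ([trim_trials()]).
#' @return data.frame with columns subject, age_group, context, cue_type,
#'   congruency, rt, err, ies, n_trials.
#' @export
compute_dvs <- function(tt) {
  if (!nrow(tt)) stop("empty trial table", call. = FALSE)
  key <- interaction(tt$subject, tt$context, tt$cue_type, tt$congruency,
                     drop = TRUE)
  cells <- split(seq_len(nrow(tt)), key)
  out <- do.call(rbind, lapply(cells, function(i) {
    cell <- tt[i, , drop = FALSE]
    scored <- cell$accuracy %in% c("correct", "incorrect")
    n_corr <- sum(cell$accuracy == "correct")
    err <- if (sum(scored)) sum(cell$accuracy == "incorrect") / sum(scored)
           else NA_real_
    rt <- if (n_corr) mean(cell$rt[cell$accuracy == "correct"]) else NA_real_
    ies <- if (!is.na(rt) && !is.na(err) && err < 1) rt / (1 - err)
           else NA_real_
    data.frame(subject = cell$subject[1], age_group = cell$age_group[1],
               context = cell$context[1], cue_type = cell$cue_type[1],
               congruency = cell$congruency[1],
               rt = rt, err = err, ies = ies, n_trials = nrow(cell),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(out$ies))
    warning(sum(is.na(out$ies)), " cell(s) without computable IES ",
            "(no correct trials)", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Congruency effect in inverse efficiency
#'
#' The per-cell cost of flanker interference: incongruent IES minus
#' congruent IES, per (subject, context, cue type). Missing congruency
#' cells yield `NA`.
#'
#' @param bt a behavior table from [compute_dvs()].
#' @return data.frame with columns subject, age_group, context, cue_type,
#'   congruency_effect (ms).
#' @export
congruency_effect <- function(bt) {
  key <- interaction(bt$subject, bt$context, bt$cue_type, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(bt)), key), function(i) {
    cell <- bt[i, , drop = FALSE]
    inc <- cell$ies[cell$congruency == "incongruent"]
    con <- cell$ies[cell$congruency == "congruent"]
    eff <- if (length(inc) == 1 && length(con) == 1) inc - con else NA_real_
    data.frame(subject = cell$subject[1], age_group = cell$age_group[1],
               context = cell$context[1], cue_type = cell$cue_type[1],
               congruency_effect = eff, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
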