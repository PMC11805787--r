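# Trial-level RT trimming, binomial-guessing thresholds, the seven level-2
# cognitive measures, and participant-level exclusion rules.

#' Reaction-time trimming rule
#'
#' A fixed window \[`rt_floor`, `rt_ceiling`\] followed by interquartile
#' fences Q1 - k*IQR and Q3 + k*IQR computed on the window-surviving values.
#' Task presets carry the windows used per task: item-probe, breadth of
#' attention and WM tasks use \[100, 3000\] ms; cueing tasks \[100, 1200\] ms.
#'
#' @param rt_floor,rt_ceiling Window bounds in ms.
#' @param fence_multiplier IQR multiplier for the fences (default 3).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return An object of class `spoarc_trim_rule`.
#' @export
trim_rule <- function(rt_floor = 100, rt_ceiling = 3000,
                      fence_multiplier = 3, quantile_type = 7) {
  stop_if_not(rt_floor < rt_ceiling, "rt_floor must be below rt_ceiling")
  stop_if_not(fence_multiplier > 0, "fence_multiplier must be positive")
  structure(list(rt_floor = rt_floor, rt_ceiling = rt_ceiling,
                 fence_multiplier = fence_multiplier,
                 quantile_type = quantile_type),
            class = "spoarc_trim_rule")
}

#' @rdname trim_rule
#' @export
trim_rule_item_probe <- function() trim_rule(100, 3000)

#' @rdname trim_rule
#' @export
trim_rule_cueing <- function() trim_rule(100, 1200)

#' @rdname trim_rule
#' @export
trim_rule_wm <- function() trim_rule(100, 3000)

#' @rdname trim_rule
#' @export
trim_rule_boa <- function() trim_rule(100, 3000)

#' Trim reaction times
#'
#' Drops RTs outside the rule's fixed window, then computes Q1/Q3/IQR on the
#' surviving values and additionally drops values outside
#' \[Q1 - k*IQR, Q3 + k*IQR\].
#'
#' @param rts Numeric vector of RTs (ms).
#' @param rule A [trim_rule()].
#' @return Logical keep-mask aligned to `rts`. If every trial is extreme an
#'   all-`FALSE` mask is returned with a warning.
#' @export
trim_rts <- function(rts, rule = trim_rule()) {
  stop_if_not(length(rts) > 0, "rts must be nonempty")
  keep <- !is.na(rts) & rts >= rule$rt_floor & rts <= rule$rt_ceiling
  if (!any(keep)) {
    warning("all trials removed by the RT window")
    return(keep)
  }
  q <- stats::quantile(rts[keep], c(0.25, 0.75), type = rule$quantile_type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - rule$fence_multiplier * iqr
  hi <- q[2] + rule$fence_multiplier * iqr
  keep & rts >= lo & rts <= hi
}

#' Exact binomial chance-level accuracy threshold
#'
#' The highest accuracy still consistent with guessing: k*/n where k* is the
#' largest k such that P(X >= k) > alpha for X ~ Binomial(n, 1/2). Accuracy
#' at or below this proportion cannot be distinguished from chance at
#' one-sided level alpha.
#'
#' @param n_trials Number of trials (>= 1).
#' @param alpha One-sided significance level in (0, 1).
#' @return The threshold proportion k*/n.
#' @export
binomial_chance_threshold <- function(n_trials, alpha = 0.05) {
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  stop_if_not(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  k <- 0:n_trials
  upper_tail <- 1 - stats::pbinom(k - 1, n_trials, 0.5)
  k_star <- max(k[upper_tail > alpha])
  k_star / n_trials
}

#' Breadth of attention from task trials
#'
#' After RT trimming, accuracy is computed at each tested cluster separation;
#' the breadth of attention is the largest tested separation whose accuracy
#' exceeds the threshold (default 75%), or 0 if none does. With
#' `monotone = TRUE` the largest separation such that all smaller tested
#' separations also exceed the threshold is returned instead.
#'
#' @param trials Data frame with columns `distance`, `rt_ms`, `correct`.
#' @param rule RT trimming rule (default the \[100, 3000\] ms window).
#' @param threshold Accuracy criterion (default 0.75).
#' @param monotone Require all smaller separations to pass too?
#' @return Breadth of attention in cm.
#' @export
compute_boa <- function(trials, rule = trim_rule_boa(), threshold = 0.75,
                        monotone = FALSE) {
  stop_if_not(nrow(trials) > 0, "no trials at any distance")
  keep <- trim_rts(trials$rt_ms, rule)
  trials <- trials[keep, , drop = FALSE]
  if (!nrow(trials)) return(0)
  acc <- tapply(trials$correct, trials$distance, mean)
  d <- as.numeric(names(acc))
  ord <- order(d)
  d <- d[ord]; acc <- as.numeric(acc)[ord]
  pass <- acc > threshold
  if (monotone) pass <- cumprod(pass) > 0
  if (!any(pass)) 0 else max(d[pass])
}

#' Cueing effect (invalid minus valid mean RT)
#'
#' @param valid_rts,invalid_rts Trimmed RT vectors for valid and invalid
#'   trials; both must be nonempty.
#' @return The cueing effect in ms; positive values indicate efficient
#'   orienting toward the cued location.
#' @export
compute_cueing_effect <- function(valid_rts, invalid_rts) {
  stop_if_not(length(valid_rts) > 0 && length(invalid_rts) > 0,
              "valid and invalid RT lists must be nonempty after trimming")
  mean(invalid_rts) - mean(valid_rts)
}

#' Cueing effect from a task trial table
#'
#' Convenience wrapper: restricts to correct non-catch trials, trims RTs with
#' the cueing-task rule, then applies [compute_cueing_effect()].
#'
#' @param trials Data frame with `trial_type` (`"valid"`/`"invalid"`/
#'   `"catch"`), `rt_ms`, `correct`.
#' @param rule RT trimming rule.
#' @return Cueing effect in ms.
#' @export
compute_cueing_from_trials <- function(trials, rule = trim_rule_cueing()) {
  t2 <- trials[trials$trial_type != "catch" & trials$correct %in% 1, ,
               drop = FALSE]
  keep <- trim_rts(t2$rt_ms, rule)
  t2 <- t2[keep, , drop = FALSE]
  compute_cueing_effect(t2$rt_ms[t2$trial_type == "valid"],
                        t2$rt_ms[t2$trial_type == "invalid"])
}

#' Item and serial-order WM capacities from sequence-matching trials
#'
#' Restricts to nonidentical trials, trims their RTs, and returns the mean
#' accuracy of item-changing trials (item capacity) and order-swapping trials
#' (order capacity).
#'
#' @param trials Data frame with `trial_type` (`"identical"`/`"item"`/
#'   `"order"`), `rt_ms`, `correct`.
#' @param rule RT trimming rule.
#' @return Named numeric vector `c(item = , order = )`.
#' @export
compute_wm_capacities <- function(trials, rule = trim_rule_wm()) {
  t2 <- trials[trials$trial_type %in% c("item", "order"), , drop = FALSE]
  stop_if_not(nrow(t2) > 0, "no nonidentical trials")
  keep <- trim_rts(t2$rt_ms, rule)
  t2 <- t2[keep, , drop = FALSE]
  item <- t2$correct[t2$trial_type == "item"]
  order <- t2$correct[t2$trial_type == "order"]
  stop_if_not(length(item) > 0 && length(order) > 0,
              "zero trials of a trial type after trimming")
  c(item = mean(item), order = mean(order))
}

#' Participant-level exclusion rules
#'
#' Applies, in order, the guessing screens of the behavioral battery:
#' * catch rule — responding to more than 30% of catch trials in a cueing
#'   task (equivalently, catch accuracy at or below the 20-trial chance
#'   threshold of 70%);
#' * task-accuracy rules — overall cueing-task accuracy at or below the exact
#'   168-trial binomial threshold; per-stimulus item-probe accuracy at or
#'   below the 80-trial threshold (58.75%);
#' * WM conjunction rule — WM task accuracy below the 120-trial threshold
#'   (57.5%) AND mean task RT below the group-level fast fence
#'   Q1 - 3*IQR of all participants' mean RTs for that task.
#'
#' @param summaries Data frame with one row per participant and columns
#'   `participant_id`, `exo_catch_rate`, `endo_catch_rate`, `exo_acc`,
#'   `endo_acc`, `consonant_acc`, `color_acc`, `vwm_acc`, `swm_acc`,
#'   `vwm_mean_rt`, `swm_mean_rt`.
#' @param alpha One-sided binomial level for the thresholds.
#' @return Data frame (`participant_id`, `kept`, `reasons`); `reasons` is a
#'   semicolon-joined list of triggered rule identifiers, empty iff kept.
#' @export
apply_exclusions <- function(summaries, alpha = 0.05) {
  need <- c("participant_id", "exo_catch_rate", "endo_catch_rate",
            "exo_acc", "endo_acc", "consonant_acc", "color_acc",
            "vwm_acc", "swm_acc", "vwm_mean_rt", "swm_mean_rt")
  missing <- setdiff(need, names(summaries))
  stop_if_not(length(missing) == 0,
              paste("missing summary fields:", paste(missing, collapse = ", ")))
  thr_cue <- binomial_chance_threshold(168, alpha)
  thr_probe <- binomial_chance_threshold(80, alpha)
  thr_wm <- binomial_chance_threshold(120, alpha)
  fence <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    q[1] - 3 * (q[2] - q[1])
  }
  vwm_fence <- fence(summaries$vwm_mean_rt)
  swm_fence <- fence(summaries$swm_mean_rt)

  reasons <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    r <- character(0)
    if (s$exo_catch_rate > 0.30) r <- c(r, "exo_catch_rate")
    if (s$endo_catch_rate > 0.30) r <- c(r, "endo_catch_rate")
    if (s$exo_acc <= thr_cue) r <- c(r, "exo_task_accuracy")
    if (s$endo_acc <= thr_cue) r <- c(r, "endo_task_accuracy")
    if (s$consonant_acc <= thr_probe) r <- c(r, "consonant_probe_accuracy")
    if (s$color_acc <= thr_probe) r <- c(r, "color_probe_accuracy")
    if (s$vwm_acc < thr_wm && s$vwm_mean_rt < vwm_fence)
      r <- c(r, "vwm_guessing_conjunction")
    if (s$swm_acc < thr_wm && s$swm_mean_rt < swm_fence)
      r <- c(r, "swm_guessing_conjunction")
    r
  })
  data.frame(
    participant_id = summaries$participant_id,
    kept = lengths(reasons) == 0,
    reasons = vapply(reasons, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}
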