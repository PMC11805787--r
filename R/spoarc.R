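# The per-participant SPoARC magnitude: the right-hand minus left-hand OLS
# slope of RT on the serial position of the probe, over correct positive-probe
# item-probe trials, pooled across both material types after per-material
# trimming. Negative values indicate the SPoARC pattern (left-hand advantage
# for early positions, right-hand advantage for late positions).

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

#' SPoARC magnitude for one participant
#'
#' Restricts to correct, positive-probe trials, trims RTs per material type
#' with the item-probe rule, then fits ordinary least-squares slopes of RT on
#' probe position separately per responding hand. The magnitude is the
#' right-hand slope minus the left-hand slope (ms per position).
#'
#' @param trials Trial data frame for a single participant with columns
#'   `task`, `hand` (+1 right / -1 left), `position`, `rt_ms`, `correct`,
#'   `probe_positive`.
#' @param rule RT trimming rule (default item-probe \[100, 3000\] ms).
#' @param min_trials Minimum usable trials per hand before the participant is
#'   flagged (not dropped).
#' @return One-row data frame: `slope_left`, `slope_right`, `magnitude`,
#'   `n_trials_used`, `flagged`. Slopes are `NA` when a hand has fewer than
#'   two distinct positions.
#' @export
spoarc_magnitude <- function(trials, rule = trim_rule_item_probe(),
                             min_trials = 5) {
  t2 <- trials[trials$correct %in% 1 & trials$probe_positive %in% 1, ,
               drop = FALSE]
  if (nrow(t2)) {
    keep <- unlist(lapply(split(seq_len(nrow(t2)), t2$task), function(ix) {
      ix[trim_rts(t2$rt_ms[ix], rule)]
    }))
    t2 <- t2[sort(keep), , drop = FALSE]
  }
  slope_for <- function(h) {
    d <- t2[t2$hand == h, , drop = FALSE]
    if (length(unique(d$position)) < 2) return(NA_real_)
    ols_slope(d$position, d$rt_ms)
  }
  sl <- slope_for(-1)
  sr <- slope_for(1)
  data.frame(
    slope_left = sl, slope_right = sr, magnitude = sr - sl,
    n_trials_used = nrow(t2),
    flagged = sum(t2$hand == 1) < min_trials | sum(t2$hand == -1) < min_trials
  )
}

#' SPoARC magnitudes for a cohort
#'
#' Applies [spoarc_magnitude()] per participant.
#'
#' @param trials Trial data frame with a `participant_id` column.
#' @inheritParams spoarc_magnitude
#' @return Data frame with one row per participant (`participant_id` plus the
#'   [spoarc_magnitude()] columns).
#' @export
spoarc_magnitudes <- function(trials, rule = trim_rule_item_probe(),
                              min_trials = 5) {
  parts <- split(trials, trials$participant_id)
  out <- do.call(rbind, lapply(parts, spoarc_magnitude, rule = rule,
                               min_trials = min_trials))
  out <- cbind(participant_id = as.vector(vapply(
    parts, function(d) d$participant_id[1],
    if (is.character(trials$participant_id)) character(1) else numeric(1))),
    out)
  rownames(out) <- NULL
  out
}

#' Group summary of SPoARC magnitudes
#'
#' Standard moment summaries of the per-participant magnitudes: mean, sample
#' SD, range, skewness and excess kurtosis (the latter two screened against
#' |skew| < 2 and |kurtosis| < 4 as an approximate-normality check).
#'
#' @param magnitudes Numeric vector of SPoARC magnitudes (>= 2 values).
#' @return Named list: `mean`, `sd`, `min`, `max`, `skew`, `kurtosis`, `n`.
#' @export
group_spoarc_summary <- function(magnitudes) {
  m <- magnitudes[is.finite(magnitudes)]
  stop_if_not(length(m) >= 2, "need at least 2 magnitudes")
  list(mean = mean(m), sd = stats::sd(m), min = min(m), max = max(m),
       skew = sample_skewness(m), kurtosis = sample_kurtosis(m),
       n = length(m))
}
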