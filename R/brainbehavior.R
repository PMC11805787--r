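# Brain-behavior correlation analyses: Pearson correlations between the
# SPoARC magnitude and network modularity, and Steiger tests comparing the
# dependent correlations obtained at different network scales.
#
# Sign convention: the SPoARC magnitude is signed (more negative = larger
# effect), so a POSITIVE correlation between modularity and the magnitude
# means lower modularity goes with a more negative (larger) SPoARC effect.

#' Pearson correlation with a two-sided t-test
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite values,
#'   non-zero variance).
#' @return List `r`, `p`, `n`, `t`, `df`.
#' @export
pearson_r <- function(x, y) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  stop_if_not(length(x) >= 3, "need n >= 3")
  stop_if_not(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       t = unname(ct$statistic), df = unname(ct$parameter))
}

#' Steiger test for two dependent correlations sharing a variable
#'
#' Compares r_jk and r_jh — the correlations of a common variable j with k
#' and h — measured on the same sample, using Steiger's Z1* statistic: the
#' difference of Fisher z transforms scaled by their dependent-samples
#' covariance, with the pooled correlation rbar = (r_jk + r_jh)/2 in the
#' covariance term:
#' psi = r_kh (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_kh^2) / 2,
#' s = psi / (1 - rbar^2)^2, and
#' Z1* = (z_jk - z_jh) sqrt(n - 3) / sqrt(2 - 2 s).
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the non-shared variables.
#' @param n Sample size (>= 4).
#' @param alternative `"two.sided"` (default), `"greater"` (r_jk > r_jh) or
#'   `"less"`.
#' @return List of class `spoarc_steiger`: `z`, `p`, `n`, `r_jk`, `r_jh`,
#'   `r_kh`, `alternative`. `z` has the sign of z(r_jk) - z(r_jh).
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if_not(n >= 4, "need n >= 4")
  stop_if_not(abs(r_jk) < 1 && abs(r_jh) < 1 && abs(r_kh) <= 1,
              "compared correlations must have |r| < 1")
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3, 3)
  stop_if_not(is_psd(R), "correlation triplet is not positive semi-definite")
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - rbar^2 * (1 - 2 * rbar^2 - r_kh^2) / 2
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt(n - 3) / sqrt(2 - 2 * s)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  structure(list(z = z, p = p, n = n, r_jk = r_jk, r_jh = r_jh, r_kh = r_kh,
                 alternative = alternative),
            class = "spoarc_steiger")
}

#' Compare brain-behavior correlations across network scales
#'
#' For each scale, the Pearson correlation between the per-participant SPoARC
#' magnitude and that scale's modularity values; then, for every pair of
#' scales, a Steiger dependent-correlation test of whether the two
#' brain-behavior correlations differ (both share the behavior variable).
#'
#' @param spoarc Data frame with `participant_id` and `magnitude`.
#' @param modularity_by_scale Named list of data frames, each with
#'   `participant_id` and `modularity`, one per network scale. All scales
#'   must cover exactly the same participants.
#' @param alternative Sidedness for the Steiger tests.
#' @return List of class `spoarc_scale_comparison`: `correlations` (scale,
#'   r, p, n) and `comparisons` (scale_a, scale_b, r_a, r_b, r_ab, z, p).
#' @export
scale_comparison <- function(spoarc, modularity_by_scale,
                             alternative = "two.sided") {
  stop_if_not(length(names(modularity_by_scale)) ==
                length(modularity_by_scale) &&
                !any(names(modularity_by_scale) == ""),
              "modularity_by_scale must be a named list")
  ids <- spoarc$participant_id
  mods <- lapply(modularity_by_scale, function(df) {
    stop_if_not(all(c("participant_id", "modularity") %in% names(df)),
                "each scale needs participant_id and modularity columns")
    stop_if_not(length(df$participant_id) == length(ids) &&
                  setequal(df$participant_id, ids),
                "participants misaligned across scales")
    df$modularity[match(ids, df$participant_id)]
  })
  beh <- spoarc$magnitude
  cors <- do.call(rbind, lapply(names(mods), function(sc) {
    pr <- pearson_r(beh, mods[[sc]])
    data.frame(scale = sc, r = pr$r, p = pr$p, n = pr$n)
  }))
  if (length(mods) < 2) {
    return(structure(list(correlations = cors, comparisons = NULL),
                     class = "spoarc_scale_comparison"))
  }
  combs <- utils::combn(names(mods), 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b <- combs[2, i]
    r_a <- stats::cor(beh, mods[[a]])
    r_b <- stats::cor(beh, mods[[b]])
    r_ab <- stats::cor(mods[[a]], mods[[b]])
    if (isTRUE(all.equal(mods[[a]], mods[[b]]))) {
      st <- list(z = 0, p = if (alternative == "two.sided") 1 else 0.5)
    } else {
      st <- steiger_test(r_a, r_b, r_ab, length(beh),
                         alternative = alternative)
    }
    data.frame(scale_a = a, scale_b = b, r_a = r_a, r_b = r_b, r_ab = r_ab,
               z = st$z, p = st$p)
  }))
  structure(list(correlations = cors, comparisons = comparisons),
            class = "spoarc_scale_comparison")
}
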