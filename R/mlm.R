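# Multilevel mixed-effects modeling of item-probe RTs: model specification,
# REML/FIML fits (via lme4/lmerTest), intraclass correlation, nested-model
# deviance comparisons, Johnson-Neyman regions of significance, and
# pick-a-point simple slopes for cross-level interactions.

#' Grand-mean center a vector
#'
#' @param x Numeric vector.
#' @return `x - mean(x)`; the output mean is 0 to machine precision.
#' @export
grand_mean_center <- function(x) {
  stop_if_not(length(x) > 0, "x must be nonempty")
  x - mean(x)
}

#' Multilevel model specification
#'
#' Describes which blocks of terms enter the RT model. The full specification
#' is: level-1 terms Hand, Position, Hand x Position, Task,
#' Task x Hand x Position; seven grand-mean-centered cognitive measures and
#' five demographic covariates at level 2; seven three-way cross-level
#' interactions (cognitive measure x Hand x Position) plus the four-way
#' siwm x ssowm x Hand x Position term; and by-participant random effects on
#' (intercept, Hand x Position, Task, Task x Hand x Position) with
#' unstructured covariance.
#'
#' @param l1 Include the level-1 predictors (FALSE gives an intercept-only
#'   fixed part, as in the null model)?
#' @param l2_cognitive,l2_controls Include the cognitive / demographic
#'   level-2 main effects?
#' @param cli Include the eight cross-level interaction terms?
#' @param random Character subset of
#'   `c("intercept", "hand_position", "task", "task_hand_position")`, or
#'   `NULL` for no random effects (ordinary least squares).
#' @param estimation `"REML"` (estimates/SEs) or `"FIML"` (fit indices and
#'   nested-model comparisons).
#' @return An object of class `spoarc_model_spec`.
#' @export
model_spec <- function(l1 = TRUE, l2_cognitive = TRUE, l2_controls = TRUE,
                       cli = TRUE,
                       random = c("intercept", "hand_position", "task",
                                  "task_hand_position"),
                       estimation = c("REML", "FIML")) {
  estimation <- match.arg(estimation)
  if (!is.null(random)) {
    bad <- setdiff(random, c("intercept", "hand_position", "task",
                             "task_hand_position"))
    stop_if_not(length(bad) == 0,
                paste("unknown random terms:", paste(bad, collapse = ", ")))
  }
  stop_if_not(!(cli && !l1), "CLI terms require the level-1 terms")
  structure(list(l1 = l1, l2_cognitive = l2_cognitive,
                 l2_controls = l2_controls, cli = cli, random = random,
                 estimation = estimation),
            class = "spoarc_model_spec")
}

#' @rdname model_spec
#' @export
null_model_spec <- function(estimation = "FIML") {
  model_spec(l1 = FALSE, l2_cognitive = FALSE, l2_controls = FALSE,
             cli = FALSE, random = "intercept", estimation = estimation)
}

# Merge trials with profiles, add product predictors and centered cognitive
# measures (centering constants returned as attributes).
prepare_mlm_data <- function(trials, profiles) {
  stop_if_not(all(trials$participant_id %in% profiles$participant_id),
              "trials reference participants missing from profiles")
  d <- merge(trials, profiles, by = "participant_id")
  d$hp <- d$hand * d$position
  d$thp <- d$task * d$hp
  centers <- vapply(cognitive_measures(), function(v) mean(profiles[[v]]),
                    numeric(1))
  sds <- vapply(cognitive_measures(), function(v) stats::sd(profiles[[v]]),
                numeric(1))
  for (v in cognitive_measures()) d[[paste0(v, "_c")]] <- d[[v]] - centers[[v]]
  attr(d, "centers") <- centers
  attr(d, "sds") <- sds
  d
}

mlm_formula <- function(spec) {
  cogs <- paste0(cognitive_measures(), "_c")
  terms <- character(0)
  if (spec$l1) terms <- c(terms, "hand", "position", "hp", "task", "thp")
  if (spec$l2_cognitive) terms <- c(terms, cogs)
  if (spec$l2_controls)
    terms <- c(terms, "handedness", "altL", "school", "education_years",
               "gender")
  if (spec$cli)
    terms <- c(terms, paste0("hp:", cogs), "hp:siwm_c:ssowm_c")
  re <- NULL
  if (length(spec$random)) {
    map <- c(intercept = "1", hand_position = "hp", task = "task",
             task_hand_position = "thp")
    re_terms <- unname(map[spec$random])
    if (!"intercept" %in% spec$random) re_terms <- c("0", re_terms)
    re <- paste0("(", paste(re_terms, collapse = " + "), " | participant_id)")
  }
  rhs <- paste(c(if (length(terms)) terms else "1", re), collapse = " + ")
  stats::as.formula(paste("rt_ms ~", rhs))
}

#' Fit the multilevel RT model
#'
#' Fits the Gaussian linear mixed model described by a [model_spec()] to the
#' merged trial/profile data: y = X gamma + Z u + e with by-participant
#' u ~ N(0, tau) (unstructured) and e ~ N(0, sigma2 I). REML is used for
#' estimates and standard errors; FIML for deviance-based fit indices and
#' nested-model comparisons. t-statistics are each coefficient divided by its
#' SE, with Satterthwaite degrees of freedom by default. With no random terms
#' the model reduces to ordinary least squares.
#'
#' @param trials Trial table (`participant_id`, `hand`, `position`, `task`,
#'   `rt_ms`, ...).
#' @param profiles Participant table with the seven cognitive measures and
#'   demographic covariates.
#' @param spec A [model_spec()].
#' @param ddf `"satterthwaite"` (default) or `"none"` (faster; normal-theory
#'   p-values, df reported as NA).
#' @param fit_indices Also refit by FIML to populate deviance/AIC/BIC when
#'   `spec$estimation == "REML"`?
#' @return An object of class `spoarc_fit`: `gamma` (term, estimate, se, df,
#'   t, p), `sigma2`, `tau`, `vcov_fixed`, `loglik`, `deviance`, `AIC`,
#'   `BIC`, `n_params`, `converged`, `singular`, plus centering metadata and
#'   the underlying model object.
#' @export
fit_lmm <- function(trials, profiles, spec = model_spec(),
                    ddf = c("satterthwaite", "none"), fit_indices = FALSE) {
  ddf <- match.arg(ddf)
  d <- prepare_mlm_data(trials, profiles)
  form <- mlm_formula(spec)

  if (!length(spec$random)) {
    fit <- stats::lm(form, data = d)
    cs <- stats::coef(summary(fit))
    gamma <- data.frame(term = rownames(cs), estimate = cs[, 1], se = cs[, 2],
                        df = fit$df.residual, t = cs[, 3], p = cs[, 4],
                        row.names = NULL)
    ll <- as.numeric(stats::logLik(fit))
    out <- list(gamma = gamma, sigma2 = summary(fit)$sigma^2, tau = NULL,
                vcov_fixed = stats::vcov(fit), loglik = ll,
                deviance = -2 * ll, AIC = stats::AIC(fit),
                BIC = stats::BIC(fit),
                n_params = length(stats::coef(fit)) + 1,
                converged = TRUE, singular = FALSE)
  } else {
    reml <- spec$estimation == "REML"
    ctrl <- lme4::lmerControl(calc.derivs = (ddf == "satterthwaite"),
                              check.conv.singular = "ignore")
    fitter <- if (ddf == "satterthwaite") lmerTest::lmer else lme4::lmer
    fit <- withCallingHandlers(
      fitter(form, data = d, REML = reml, control = ctrl),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
    cs <- stats::coef(summary(fit))
    if (ddf == "satterthwaite") {
      gamma <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                          se = cs[, "Std. Error"], df = cs[, "df"],
                          t = cs[, "t value"], p = cs[, "Pr(>|t|)"],
                          row.names = NULL)
    } else {
      tval <- cs[, "t value"]
      gamma <- data.frame(term = rownames(cs), estimate = cs[, "Estimate"],
                          se = cs[, "Std. Error"], df = NA_real_, t = tval,
                          p = 2 * stats::pnorm(-abs(tval)), row.names = NULL)
    }
    vc <- lme4::VarCorr(fit)
    tau <- as.matrix(Matrix_to_base(vc$participant_id))
    sigma2 <- attr(vc, "sc")^2
    n_params <- length(lme4::fixef(fit)) + length(lme4::getME(fit, "theta")) + 1
    ll <- as.numeric(stats::logLik(fit))
    dev <- AICv <- BICv <- NA_real_
    if (!reml) {
      dev <- -2 * ll; AICv <- stats::AIC(fit); BICv <- stats::BIC(fit)
    } else if (fit_indices) {
      fitF <- withCallingHandlers(
        lme4::lmer(form, data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore")),
        warning = function(w) invokeRestart("muffleWarning"))
      llF <- as.numeric(stats::logLik(fitF))
      dev <- -2 * llF; AICv <- stats::AIC(fitF); BICv <- stats::BIC(fitF)
    }
    conv <- is.null(fit@optinfo$conv$lme4$code)
    out <- list(gamma = gamma, sigma2 = sigma2, tau = tau,
                vcov_fixed = as.matrix(stats::vcov(fit)), loglik = ll,
                deviance = dev, AIC = AICv, BIC = BICv, n_params = n_params,
                converged = conv, singular = lme4::isSingular(fit))
  }
  out$spec <- spec
  out$centers <- attr(d, "centers")
  out$sds <- attr(d, "sds")
  out$task_mean <- mean(d$task)
  out$n_l1 <- nrow(d)
  out$n_l2 <- length(unique(d$participant_id))
  out$model <- fit
  out$formula <- form
  class(out) <- "spoarc_fit"
  out
}

# strip Matrix/VarCorr attributes to a plain base matrix
Matrix_to_base <- function(m) {
  out <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

#' @export
print.spoarc_fit <- function(x, ...) {
  cat("Multilevel RT model fit (", x$spec$estimation, ")\n", sep = "")
  cat("  L1 n =", x$n_l1, " L2 n =", x$n_l2, "\n")
  g <- x$gamma
  g[, -1] <- lapply(g[, -1], function(v) round(v, 3))
  print(g, row.names = FALSE)
  if (!is.null(x$tau)) {
    cat("Residual variance sigma2 =", round(x$sigma2, 1), "\n")
    cat("Random-effect covariance tau:\n")
    print(round(x$tau, 1))
  }
  if (is.finite(x$deviance))
    cat("Deviance =", round(x$deviance, 1), " AIC =", round(x$AIC, 1),
        " BIC =", round(x$BIC, 1), " params =", x$n_params, "\n")
  invisible(x)
}

gamma_of <- function(fit, term) {
  i <- match(term, fit$gamma$term)
  stop_if_not(!is.na(i), paste("coefficient not in fit:", term))
  i
}

#' Intraclass correlation from the null model
#'
#' tau00 / (tau00 + sigma2): the fraction of RT variance attributable to
#' between-participant differences.
#'
#' @param null_fit A [fit_lmm()] result with intercept-only random structure.
#' @return The ICC as a proportion.
#' @export
icc <- function(null_fit) {
  stop_if_not(identical(null_fit$spec$random, "intercept"),
              "icc requires an intercept-only random structure")
  tau00 <- null_fit$tau[1, 1]
  tau00 / (tau00 + null_fit$sigma2)
}

#' Compare two nested model fits by their FIML deviances
#'
#' Delta-deviance chi-squared test: chi2 = D_reduced - D_full with df equal
#' to the parameter-count difference. Fits estimated by REML are refitted by
#' FIML first.
#'
#' @param fit_reduced,fit_full Nested [fit_lmm()] results (reduced within
#'   full).
#' @return List `chi2`, `df`, `p`, and the two FIML deviances.
#' @export
compare_models <- function(fit_reduced, fit_full) {
  dev_of <- function(f) {
    if (is.finite(f$deviance)) return(f$deviance)
    m <- f$model
    stop_if_not(inherits(m, "merMod"), "cannot refit: model object missing")
    m2 <- withCallingHandlers(
      lme4::refitML(m), warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage"))
    -2 * as.numeric(stats::logLik(m2))
  }
  d1 <- dev_of(fit_reduced)
  d2 <- dev_of(fit_full)
  df <- fit_full$n_params - fit_reduced$n_params
  stop_if_not(df >= 0, "models are not nested (reduced has more parameters)")
  chi2 <- d1 - d2
  if (chi2 < -1e-6)
    warning("negative chi-squared: possible convergence failure")
  p <- if (df == 0) NA_real_ else stats::pchisq(max(chi2, 0), df,
                                                lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, deviance_reduced = d1, deviance_full = d2)
}

#' Johnson-Neyman region of significance (closed form)
#'
#' For the conditional effect omega(w) = gamma_f + gamma_c w of a focal term
#' moderated by w, solves |omega(w)| / SE(omega(w)) = crit, i.e. the quadratic
#' (gamma_c^2 - crit^2 v_cc) w^2 + 2(gamma_f gamma_c - crit^2 v_fc) w +
#' (gamma_f^2 - crit^2 v_ff) = 0, and reports the sub-ranges of the moderator
#' where the conditional effect is significant.
#'
#' @param gamma_f,gamma_c Focal and interaction coefficients.
#' @param v_ff,v_fc,v_cc Variance of the focal coefficient, its covariance
#'   with the interaction coefficient, and the interaction variance.
#' @param crit Critical value of the test statistic.
#' @param range Optional moderator range (length 2) to intersect with.
#' @return List of class `spoarc_jn`: `boundaries` (sorted real roots, up to
#'   2), `significant` (matrix of significant intervals, columns lo/hi),
#'   `crit`.
#' @export
jn_region <- function(gamma_f, gamma_c, v_ff, v_fc, v_cc, crit,
                      range = NULL) {
  stop_if_not(v_ff > 0 && v_cc >= 0, "variance terms must be positive")
  a <- gamma_c^2 - crit^2 * v_cc
  b <- 2 * (gamma_f * gamma_c - crit^2 * v_fc)
  cc <- gamma_f^2 - crit^2 * v_ff
  roots <- numeric(0)
  if (abs(a) > 1e-300) {
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  } else if (abs(b) > 1e-300) {
    roots <- -cc / b
  }
  tratio <- function(w)
    abs(gamma_f + gamma_c * w) / sqrt(v_ff + 2 * w * v_fc + w^2 * v_cc)
  lo_ref <- if (is.null(range)) min(c(roots, 0)) - 1 else range[1]
  hi_ref <- if (is.null(range)) max(c(roots, 0)) + 1 else range[2]
  breaks <- sort(unique(c(lo_ref, roots[roots > lo_ref & roots < hi_ref],
                          hi_ref)))
  sig <- NULL
  for (i in seq_len(length(breaks) - 1)) {
    mid <- (breaks[i] + breaks[i + 1]) / 2
    if (tratio(mid) > crit) sig <- rbind(sig, c(breaks[i], breaks[i + 1]))
  }
  if (length(breaks) == 1 && tratio(breaks) > crit)
    sig <- rbind(sig, c(breaks, breaks))
  # merge adjacent intervals
  if (!is.null(sig) && nrow(sig) > 1) {
    merged <- sig[1, , drop = FALSE]
    for (i in 2:nrow(sig)) {
      if (abs(sig[i, 1] - merged[nrow(merged), 2]) < 1e-12)
        merged[nrow(merged), 2] <- sig[i, 2]
      else merged <- rbind(merged, sig[i, ])
    }
    sig <- merged
  }
  if (!is.null(sig)) colnames(sig) <- c("lo", "hi")
  structure(list(boundaries = roots, significant = sig, crit = crit),
            class = "spoarc_jn")
}

#' Johnson-Neyman region for a fitted model's cross-level interaction
#'
#' Extracts the Hand x Position coefficient, the moderator's cross-level
#' interaction coefficient and their covariance from a fit and applies
#' [jn_region()]. The critical value is a t quantile at the interaction
#' coefficient's Satterthwaite df (normal when df are unavailable or
#' `use_t = FALSE`). Boundaries and ranges are on the centered moderator
#' scale unless `centered = FALSE`, in which case they are shifted by the
#' moderator's grand mean.
#'
#' @param fit A [fit_lmm()] result including CLI terms.
#' @param moderator Cognitive measure name (e.g. `"vsowm"`).
#' @param focal Focal coefficient name (default `"hp"`, Hand x Position).
#' @param alpha Two-sided significance level.
#' @param range Optional observed moderator range to intersect with (on the
#'   scale selected by `centered`).
#' @param use_t Use the t distribution (default) or the normal.
#' @param centered Report on the centered moderator scale?
#' @return A `spoarc_jn` object (see [jn_region()]) with the moderator name
#'   and alpha attached.
#' @export
johnson_neyman <- function(fit, moderator, focal = "hp", alpha = 0.05,
                           range = NULL, use_t = TRUE, centered = FALSE) {
  cli_term <- paste0("hp:", moderator, "_c")
  i_f <- gamma_of(fit, focal)
  i_c <- gamma_of(fit, cli_term)
  g <- fit$gamma
  V <- fit$vcov_fixed
  df <- g$df[i_c]
  crit <- if (use_t && is.finite(df)) stats::qt(1 - alpha / 2, df)
          else stats::qnorm(1 - alpha / 2)
  shift <- if (centered) 0 else unname(fit$centers[moderator])
  r <- if (is.null(range)) NULL else range - shift
  out <- jn_region(g$estimate[i_f], g$estimate[i_c],
                   V[i_f, i_f], V[i_f, i_c], V[i_c, i_c], crit, range = r)
  out$boundaries <- out$boundaries + shift
  if (!is.null(out$significant)) out$significant <- out$significant + shift
  out$moderator <- moderator
  out$alpha <- alpha
  out
}

#' Pick-a-point simple slopes of Position by hand
#'
#' Evaluates, at chosen moderator levels, the conditional slope of Position
#' for each hand and their right-minus-left difference, with delta-method
#' standard errors from the fixed-effect covariance. The slope for hand h at
#' centered moderator value w is gamma_Position + h (gamma_HandxPosition +
#' gamma_CLI w + gamma_TaskxHandxPosition t), evaluated at task value t
#' (default: the sample mean of Task). Default levels are the moderator's
#' mean - SD, mean, and mean + SD, optionally restricted to a
#' Johnson-Neyman region.
#'
#' @param fit A [fit_lmm()] result including CLI terms.
#' @param moderator Cognitive measure name (e.g. `"vsowm"`).
#' @param levels Moderator levels on the original (uncentered) scale;
#'   default mean +- SD.
#' @param task_value Task covariate value at which slopes are evaluated.
#' @param restrict Optional length-2 bounds (uncentered scale, e.g. a JN
#'   region); levels outside are dropped with a warning.
#' @return Data frame of class `spoarc_simple_slopes`: `level`,
#'   `slope_left`, `slope_right`, `diff`, `se_diff`. A negative `diff`
#'   (right minus left) indicates the SPoARC pattern.
#' @export
simple_slopes <- function(fit, moderator, levels = NULL, task_value = NULL,
                          restrict = NULL) {
  center <- unname(fit$centers[moderator])
  sdm <- unname(fit$sds[moderator])
  if (is.null(levels)) levels <- center + c(-1, 0, 1) * sdm
  if (!is.null(restrict)) {
    drop <- levels < restrict[1] | levels > restrict[2]
    if (any(drop)) {
      warning("levels outside the requested region dropped")
      levels <- levels[!drop]
    }
  }
  task_value <- task_value %||% fit$task_mean
  g <- fit$gamma
  V <- fit$vcov_fixed
  cli_term <- paste0("hp:", moderator, "_c")
  i_pos <- gamma_of(fit, "position")
  i_hp <- gamma_of(fit, "hp")
  i_cli <- gamma_of(fit, cli_term)
  i_thp <- match("thp", g$term)
  out <- do.call(rbind, lapply(levels, function(lev) {
    w <- lev - center
    L_h <- function(h) {
      L <- numeric(nrow(g))
      L[i_pos] <- 1
      L[i_hp] <- h
      L[i_cli] <- h * w
      if (!is.na(i_thp)) L[i_thp] <- h * task_value
      L
    }
    Ld <- L_h(1) - L_h(-1)
    data.frame(
      level = lev,
      slope_left = sum(L_h(-1) * g$estimate),
      slope_right = sum(L_h(1) * g$estimate),
      diff = sum(Ld * g$estimate),
      se_diff = sqrt(drop(t(Ld) %*% V %*% Ld))
    )
  }))
  class(out) <- c("spoarc_simple_slopes", class(out))
  out
}
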