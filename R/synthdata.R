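# Synthetic-data generators emulating the study conditions of the
# two-experiment design: 160 participants, seven level-2 cognitive measures
# with a known rank-correlation structure, 44-79 item-probe trials per
# participant generated from a multilevel RT model, attention and WM task
# batteries, and multi-run node time series with planted community structure.

#' Default moments of the seven level-2 cognitive measures
#'
#' Marginal means, SDs and observed ranges for the seven individual-difference
#' measures: breadth of attention (`boa`, cm), exogenous and endogenous cueing
#' effects (`exo`, `endo`, ms), and verbal/spatial item and serial-order WM
#' capacities (`viwm`, `vsowm`, `siwm`, `ssowm`, proportions correct).
#'
#' @return A data.frame with columns `measure`, `mean`, `sd`, `min`, `max`.
#' @export
default_l2_moments <- function() {
  data.frame(
    measure = c("boa", "exo", "endo", "viwm", "vsowm", "siwm", "ssowm"),
    mean = c(77.15, 33.54, 36.52, 0.70, 0.65, 0.81, 0.66),
    sd   = c(11.31, 34.49, 35.97, 0.13, 0.18, 0.16, 0.19),
    min  = c(28.70, -64.01, -42.04, 0.32, 0.21, 0.29, 0.27),
    max  = c(88.30, 132.05, 149.45, 0.96, 0.97, 1.00, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Default rank-correlation matrix of the level-2 cognitive measures
#'
#' Pairwise Spearman correlations among the seven cognitive measures, used as
#' copula targets by [generate_participants()].
#'
#' @return A symmetric 7x7 correlation matrix with unit diagonal.
#' @export
default_l2_correlations <- function() {
  nm <- c("boa", "exo", "endo", "viwm", "vsowm", "siwm", "ssowm")
  r <- diag(7)
  dimnames(r) <- list(nm, nm)
  lower <- list(
    exo   = c(boa = 0.00),
    endo  = c(boa = -0.02, exo = 0.20),
    viwm  = c(boa = 0.05, exo = -0.21, endo = 0.05),
    vsowm = c(boa = 0.03, exo = -0.22, endo = 0.03, viwm = 0.59),
    siwm  = c(boa = -0.10, exo = -0.18, endo = 0.09, viwm = 0.32, vsowm = 0.30),
    ssowm = c(boa = -0.07, exo = -0.22, endo = 0.00, viwm = 0.31, vsowm = 0.40,
              siwm = 0.66)
  )
  for (row in names(lower)) for (col in names(lower[[row]])) {
    r[row, col] <- r[col, row] <- lower[[row]][[col]]
  }
  r
}

#' Default fixed effects of the generating multilevel RT model
#'
#' Named vector of unstandardized fixed effects on RT (ms): level-1 terms
#' (intercept, Hand coded +1 right / -1 left, Position 1-5, Hand x Position,
#' Task coded 1/2, Task x Hand x Position), main effects of the seven
#' grand-mean-centered cognitive measures, five demographic covariates, the
#' seven three-way cross-level interactions with Hand x Position, and the
#' four-way siwm x ssowm x Hand x Position term.
#'
#' @return Named numeric vector of generating coefficients.
#' @export
default_fixed_effects <- function() {
  c(
    intercept = 1210.44,
    hand = 32.17, position = -37.37, hand_position = -23.27,
    task = -69.63, task_hand_position = 11.27,
    boa = 0.99, exo = 1.2, endo = -0.61,
    viwm = 58.34, vsowm = 183.36, siwm = 39.16, ssowm = -114.9,
    handedness = 119.4, altL = 30.76, school = 7.68,
    education_years = -29.56, gender = 66.99,
    cli_boa = 0.13, cli_exo = -0.02, cli_endo = 0.02,
    cli_viwm = 9.72, cli_vsowm = -19.37, cli_siwm = -24.25, cli_ssowm = 17.84,
    cli_siwm_ssowm = -100.39
  )
}

#' Default variance components of the generating multilevel RT model
#'
#' Residual variance `sigma2` and the unstructured 4x4 by-participant
#' random-effect covariance `tau` over (intercept, Hand x Position, Task,
#' Task x Hand x Position).
#'
#' @return List with elements `sigma2` (scalar) and `tau` (4x4 matrix).
#' @export
default_variance_components <- function() {
  nm <- c("intercept", "hand_position", "task", "task_hand_position")
  tau <- matrix(c(
    100786.00, -5425.88, -41676.41, 3360.10,
    -5425.88, 1001.40, 2256.99, -574.26,
    -41676.41, 2256.99, 26267.80, -1531.56,
    3360.10, -574.26, -1531.56, 357.20
  ), 4, 4, dimnames = list(nm, nm))
  list(sigma2 = 76098.40, tau = tau)
}

#' Generator configuration
#'
#' Bundles every parameter the synthetic-data generators use. Defaults are the
#' study conditions: 160 participants with 44-79 item-probe trials each, the
#' published level-2 moments and rank correlations, and the published fixed
#' effects and variance components of the RT model.
#'
#' @param n_participants Number of participants.
#' @param trials_range Integer interval (length 2) for per-participant
#'   item-probe trial counts; must lie within \[1, 160\].
#' @param fixed_effects Named vector as in [default_fixed_effects()].
#' @param l2_moments Data frame as in [default_l2_moments()].
#' @param l2_correlations Symmetric Spearman correlation matrix over the seven
#'   cognitive measures.
#' @param sigma2,tau Residual variance and 4x4 random-effect covariance.
#' @param negative_rt `"redraw"` (default) re-draws the residual of a trial
#'   whose RT comes out non-positive; `"floor"` clamps it at 1 ms. The choice
#'   and the number of affected draws are recorded in the ground truth.
#' @param repair_corr If the correlation matrix (after the copula transform)
#'   is not positive semi-definite, `TRUE` repairs it to the nearest PSD
#'   matrix with a warning; `FALSE` rejects it with an error.
#' @param seed Integer seed used by generators when they are not given one.
#' @return An object of class `spoarc_gen_config`.
#' @export
gen_config <- function(n_participants = 160,
                       trials_range = c(44L, 79L),
                       fixed_effects = default_fixed_effects(),
                       l2_moments = default_l2_moments(),
                       l2_correlations = default_l2_correlations(),
                       sigma2 = default_variance_components()$sigma2,
                       tau = default_variance_components()$tau,
                       negative_rt = c("redraw", "floor"),
                       repair_corr = TRUE,
                       seed = 1L) {
  negative_rt <- match.arg(negative_rt)
  stop_if_not(n_participants >= 1, "n_participants must be >= 1")
  trials_range <- as.integer(round(trials_range))
  stop_if_not(length(trials_range) == 2 && trials_range[1] <= trials_range[2],
              "trials_range must be an ordered integer interval")
  stop_if_not(trials_range[1] >= 1 && trials_range[2] <= 160,
              "trials_range must lie within [1, 160]")
  stop_if_not(all(names(default_fixed_effects()) %in% names(fixed_effects)),
              "fixed_effects is missing required coefficients")
  stop_if_not(isTRUE(all.equal(l2_correlations, t(l2_correlations))) &&
                all(abs(diag(l2_correlations) - 1) < 1e-12),
              "l2_correlations must be symmetric with unit diagonal")
  stop_if_not(sigma2 >= 0, "sigma2 must be non-negative")
  stop_if_not(is_psd(tau), "tau must be positive semi-definite")
  structure(
    list(
      n_participants = as.integer(n_participants),
      trials_range = trials_range,
      fixed_effects = fixed_effects,
      l2_moments = l2_moments,
      l2_correlations = l2_correlations,
      sigma2 = sigma2,
      tau = tau,
      negative_rt = negative_rt,
      repair_corr = repair_corr,
      seed = as.integer(seed)
    ),
    class = "spoarc_gen_config"
  )
}

#' Generate participant profiles
#'
#' Draws the seven cognitive measures from a Gaussian copula whose latent
#' correlation reproduces the configured Spearman targets, with Gaussian
#' marginals at the configured means/SDs truncated to the observed
#' \[min, max\] by re-drawing violating rows. Demographic covariates use the
#' study codings: handedness (1 left / 2 right), gender (1 male / 2 female),
#' altL (1 if exposed to a right-to-left or spatially expressed language),
#' school (site code 1/2) and education years.
#'
#' @param config A [gen_config()] object.
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return Data frame of participant profiles, one row per participant.
#' @export
generate_participants <- function(config = gen_config(), seed = NULL) {
  set.seed(seed %||% config$seed)
  n <- config$n_participants
  mom <- config$l2_moments
  r_lat <- spearman_to_pearson(config$l2_correlations)
  if (!is_psd(r_lat)) {
    if (config$repair_corr) {
      warning("latent correlation matrix not PSD; repaired to nearest PSD")
      r_lat <- nearest_psd(r_lat, corr = TRUE)
    } else {
      stop("latent correlation matrix is not positive semi-definite")
    }
  }
  p <- nrow(mom)
  draw_rows <- function(m) {
    z <- draw_mvn(m, rep(0, p), r_lat)
    sweep(sweep(z, 2, mom$sd, `*`), 2, mom$mean, `+`)
  }
  x <- draw_rows(n)
  for (iter in 1:200) {
    bad <- which(apply(x, 1, function(row)
      any(row < mom$min) || any(row > mom$max)))
    if (!length(bad)) break
    x[bad, ] <- draw_rows(length(bad))
  }
  x <- pmin(pmax(x, matrix(mom$min, n, p, byrow = TRUE)),
            matrix(mom$max, n, p, byrow = TRUE))
  colnames(x) <- mom$measure
  out <- data.frame(participant_id = seq_len(n), x)
  out$handedness <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.07, 0.93))
  out$altL <- stats::rbinom(n, 1L, 6 / 160)
  out$education_years <- round(stats::rnorm(n, 13.5, 1.2), 1)
  out$gender <- sample(c(1L, 2L), n, replace = TRUE, prob = c(73, 87) / 160)
  out$school <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.7, 0.3))
  out
}

cognitive_measures <- function() c("boa", "exo", "endo", "viwm", "vsowm",
                                   "siwm", "ssowm")

#' Generate item-probe trials from the multilevel RT model
#'
#' For each participant, draws a trial count uniformly on the configured range
#' and generates RTs from the multilevel model: a linear predictor in Hand
#' (+1/-1), Position (1-5), Task (1 consonant / 2 color), their configured
#' interactions, participant-level main effects and cross-level interactions
#' of the grand-mean-centered cognitive measures, plus by-participant random
#' effects drawn from `tau` on (intercept, Hand x Position, Task,
#' Task x Hand x Position) and a Gaussian residual with variance `sigma2`.
#' Cognitive predictors are centered at the realized sample mean, matching the
#' grand-mean centering applied at analysis time. Non-positive RTs are
#' re-drawn (or floored) per the config.
#'
#' All generated trials represent correct positive-probe responses, the trial
#' population entering downstream analyses.
#'
#' @param profiles Output of [generate_participants()].
#' @param config A [gen_config()] object.
#' @param seed Optional integer seed.
#' @return Data frame of trials (`participant_id`, `task`, `hand`, `position`,
#'   `rt_ms`, `correct`, `probe_positive`) with a `"ground_truth"` attribute
#'   holding the config, realized random effects, centering constants and the
#'   negative-RT handling tally.
#' @export
generate_probe_trials <- function(profiles, config = gen_config(), seed = NULL) {
  stop_if_not(nrow(profiles) > 0, "profiles must be nonempty")
  set.seed(seed %||% config$seed)
  fx <- config$fixed_effects
  n <- nrow(profiles)
  centers <- vapply(cognitive_measures(), function(v) mean(profiles[[v]]),
                    numeric(1))
  cent <- as.matrix(profiles[cognitive_measures()])
  cent <- sweep(cent, 2, centers, `-`)

  u <- draw_mvn(n, rep(0, 4), config$tau)
  colnames(u) <- c("u0", "u3", "u4", "u5")

  count_choices <- seq.int(config$trials_range[1], config$trials_range[2])
  n_trials <- count_choices[sample.int(length(count_choices), n,
                                       replace = TRUE)]
  idx <- rep(seq_len(n), n_trials)
  m <- length(idx)
  hand <- sample(c(-1, 1), m, replace = TRUE)
  position <- sample(1:5, m, replace = TRUE)
  task <- sample(c(1, 2), m, replace = TRUE)
  hp <- hand * position
  thp <- task * hp

  # participant-specific Hand x Position slope: fixed part + CLIs
  cli <- fx["hand_position"] +
    cent[, "boa"] * fx["cli_boa"] + cent[, "exo"] * fx["cli_exo"] +
    cent[, "endo"] * fx["cli_endo"] + cent[, "viwm"] * fx["cli_viwm"] +
    cent[, "vsowm"] * fx["cli_vsowm"] + cent[, "siwm"] * fx["cli_siwm"] +
    cent[, "ssowm"] * fx["cli_ssowm"] +
    cent[, "siwm"] * cent[, "ssowm"] * fx["cli_siwm_ssowm"]
  l2_main <- fx["intercept"] +
    cent %*% fx[c("boa", "exo", "endo", "viwm", "vsowm", "siwm", "ssowm")] +
    profiles$handedness * fx["handedness"] + profiles$altL * fx["altL"] +
    profiles$school * fx["school"] +
    profiles$education_years * fx["education_years"] +
    profiles$gender * fx["gender"]

  mu <- l2_main[idx] + fx["hand"] * hand + fx["position"] * position +
    cli[idx] * hp + fx["task"] * task + fx["task_hand_position"] * thp +
    u[idx, "u0"] + u[idx, "u3"] * hp + u[idx, "u4"] * task + u[idx, "u5"] * thp

  sigma <- sqrt(config$sigma2)
  rt <- mu + stats::rnorm(m, 0, sigma)
  n_bad <- 0L
  if (sigma > 0) {
    for (iter in 1:100) {
      bad <- which(rt <= 0)
      if (!length(bad)) break
      n_bad <- n_bad + length(bad)
      if (config$negative_rt == "redraw") {
        rt[bad] <- mu[bad] + stats::rnorm(length(bad), 0, sigma)
      } else {
        rt[bad] <- 1
        break
      }
    }
    rt[rt <= 0] <- 1  # safety for pathological linear predictors
  }

  trials <- data.frame(
    participant_id = profiles$participant_id[idx],
    task = task, hand = hand, position = position,
    rt_ms = as.numeric(rt), correct = 1L, probe_positive = 1L
  )
  attr(trials, "ground_truth") <- list(
    config = config,
    random_effects = data.frame(participant_id = profiles$participant_id, u),
    centers = centers,
    negative_rt = config$negative_rt,
    n_negative_rt = n_bad
  )
  trials
}

#' Generate attention and working-memory task trial tables
#'
#' Emulates the five capacity tasks feeding the level-2 measures:
#' * breadth of attention — 132 trials (33 cluster separations x 4), accuracy
#'   a decreasing logistic in separation crossing 75% exactly at the profile's
#'   `boa`;
#' * exogenous/endogenous cueing — 168 trials each (126 valid, 22 invalid,
#'   20 catch); invalid-trial RTs exceed valid-trial RTs by the profile's
#'   `exo`/`endo` plus Gaussian noise;
#' * verbal and spatial sequence-matching WM — 120 trials each (40 identical,
#'   40 item-change, 40 order-swap); per-type Bernoulli accuracy with success
#'   probability equal to the profile's capacity.
#'
#' @param profiles Output of [generate_participants()].
#' @param config A [gen_config()] object (seed source).
#' @param seed Optional integer seed.
#' @param rt_base,rt_sd Mean and SD (ms) of valid-trial detection RTs in the
#'   cueing tasks.
#' @param boa_slope Logistic slope (cm) of the breadth-of-attention accuracy
#'   profile.
#' @param catch_response_rate Probability of (incorrectly) responding on a
#'   catch trial.
#' @return Named list of trial data frames: `boa`, `exo`, `endo`,
#'   `wm_verbal`, `wm_spatial`.
#' @export
generate_attention_wm_trials <- function(profiles, config = gen_config(),
                                         seed = NULL, rt_base = 350,
                                         rt_sd = 30, boa_slope = 2,
                                         catch_response_rate = 0.05) {
  stop_if_not(nrow(profiles) > 0, "profiles must be nonempty")
  set.seed(seed %||% config$seed)
  distances <- boa_distance_grid()
  n <- nrow(profiles)

  boa <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- rep(distances, each = 4)
    p <- 0.5 + 0.5 * stats::plogis((profiles$boa[i] - d) / boa_slope)
    data.frame(
      participant_id = profiles$participant_id[i],
      distance = d,
      rt_ms = pmax(stats::rnorm(length(d), 900, 200), 150),
      correct = stats::rbinom(length(d), 1L, p)
    )
  }))

  cueing <- function(effect) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      type <- sample(rep(c("valid", "invalid", "catch"), c(126L, 22L, 20L)))
      rt <- stats::rnorm(168, rt_base + ifelse(type == "invalid", effect[i], 0),
                         rt_sd)
      rt[type == "catch"] <- NA_real_
      data.frame(
        participant_id = profiles$participant_id[i],
        trial_type = type,
        rt_ms = rt,
        responded = ifelse(type == "catch",
                           stats::rbinom(168, 1L, catch_response_rate), 1L),
        correct = ifelse(type == "catch", NA_integer_, 1L)
      )
    }))
  }
  exo <- cueing(profiles$exo)
  endo <- cueing(profiles$endo)

  wm <- function(item_cap, order_cap) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      type <- sample(rep(c("identical", "item", "order"), each = 40L))
      p <- c(identical = 0.9, item = item_cap[i], order = order_cap[i])[type]
      data.frame(
        participant_id = profiles$participant_id[i],
        trial_type = type,
        rt_ms = pmax(stats::rnorm(120, 1200, 300), 150),
        correct = stats::rbinom(120, 1L, p)
      )
    }))
  }
  list(
    boa = boa, exo = exo, endo = endo,
    wm_verbal = wm(profiles$viwm, profiles$vsowm),
    wm_spatial = wm(profiles$siwm, profiles$ssowm)
  )
}

#' Tested cluster-separation grid of the breadth-of-attention task
#'
#' Thirty-three equally spaced separations up to 86.8 cm.
#'
#' @return Numeric vector of 33 separations (cm).
#' @export
boa_distance_grid <- function() seq(86.8 / 33, 86.8, length.out = 33)

#' Generate multi-run node time series with planted community structure
#'
#' Each node's series decomposes its signal coupling between a
#' module-specific latent and a global latent shared by all nodes:
#' `x = (coupling_within - coupling_between) * f_module +
#' coupling_between * g + noise`, with unit Gaussian noise and latents
#' redrawn per run. With `coupling_between = 0` the correlation structure is
#' purely modular; as `coupling_between` approaches `coupling_within` the
#' module-specific component vanishes and the network loses its planted
#' structure entirely (within- and between-module correlations coincide, so
#' the planted partition's modularity tends to zero).
#'
#' @param n_nodes Number of nodes.
#' @param membership Integer vector of planted module labels covering all
#'   nodes (length `n_nodes`).
#' @param coupling_within Total signal coupling (> 0).
#' @param coupling_between Globally shared part of the signal coupling,
#'   in \[0, `coupling_within`\].
#' @param runs Number of runs (default 3, mirroring a three-run resting-state
#'   acquisition).
#' @param timepoints Time points per run (default 420).
#' @param seed Integer seed.
#' @return A `runs x n_nodes x timepoints` array of class `spoarc_panel` with
#'   the planted membership attached as attribute `"membership"`.
#' @export
generate_modular_timeseries <- function(n_nodes, membership, coupling_within,
                                        coupling_between, runs = 3,
                                        timepoints = 420, seed = 1L) {
  stop_if_not(length(membership) == n_nodes,
              "membership must label every node")
  stop_if_not(coupling_between >= 0 && coupling_within >= 0,
              "couplings must be non-negative")
  stop_if_not(coupling_between <= coupling_within,
              "coupling_between must not exceed coupling_within")
  stop_if_not(timepoints >= 2, "need at least 2 timepoints per run")
  set.seed(seed)
  w_mod <- coupling_within - coupling_between
  mods <- sort(unique(membership))
  x <- array(0, dim = c(runs, n_nodes, timepoints))
  for (r in seq_len(runs)) {
    latent <- matrix(stats::rnorm(length(mods) * timepoints),
                     length(mods), timepoints)
    global <- stats::rnorm(timepoints)
    for (i in seq_len(n_nodes)) {
      mi <- match(membership[i], mods)
      x[r, i, ] <- w_mod * latent[mi, ] +
        coupling_between * global + stats::rnorm(timepoints)
    }
  }
  structure(x, membership = membership, class = "spoarc_panel")
}

#' Generate correlated brain-behavior samples
#'
#' Bivariate draws at a requested correlation, or trivariate draws at a
#' requested 3x3 correlation matrix for dependent-correlation tests.
#'
#' @param n Sample size.
#' @param true_r Target correlation (|r| <= 1); ignored when `corr_matrix`
#'   is supplied.
#' @param seed Integer seed.
#' @param corr_matrix Optional 3x3 (or larger) PSD correlation matrix.
#' @return A numeric matrix with one column per variable.
#' @export
generate_brain_behavior_pairs <- function(n, true_r = 0, seed = 1L,
                                          corr_matrix = NULL) {
  set.seed(seed)
  if (is.null(corr_matrix)) {
    stop_if_not(abs(true_r) <= 1, "|true_r| must be <= 1")
    corr_matrix <- matrix(c(1, true_r, true_r, 1), 2, 2)
  }
  stop_if_not(is_psd(corr_matrix), "correlation matrix must be PSD")
  x <- draw_mvn(n, rep(0, ncol(corr_matrix)), corr_matrix)
  colnames(x) <- colnames(corr_matrix) %||%
    paste0("v", seq_len(ncol(corr_matrix)))
  x
}
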