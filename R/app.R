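# Orchestration of the two experiment pipelines over synthetic cohorts:
# Experiment 1 (behavioral battery -> multilevel moderation model) and
# Experiment 2 (time-series panels -> network modularity -> SPoARC
# correlations across scales).

#' Run the behavioral (moderation-model) experiment end to end
#'
#' Generates a participant cohort and item-probe trials from the configured
#' multilevel model, fits the null (intercept-only) and full moderation
#' models, computes the ICC and the null-vs-full deviance comparison, and
#' probes the requested cross-level interactions with Johnson-Neyman regions
#' and pick-a-point simple slopes.
#'
#' @param config A [gen_config()]; its defaults are the study conditions
#'   (160 participants, 44-79 trials each, published coefficients).
#' @param seed Integer seed (defaults to `config$seed`).
#' @param moderators Cognitive measures whose CLIs are probed.
#' @param ddf Degrees-of-freedom method for [fit_lmm()].
#' @param out_dir Optional directory; when given, profiles, trials, the
#'   coefficient table and the JN/simple-slope report are written there.
#' @return List: `profiles`, `trials`, `fit`, `null_fit`, `icc`,
#'   `comparison`, `jn` (per moderator), `slopes` (per moderator).
#' @export
run_experiment1 <- function(config = gen_config(), seed = NULL,
                            moderators = c("vsowm", "siwm", "ssowm"),
                            ddf = "satterthwaite", out_dir = NULL) {
  seed <- seed %||% config$seed
  profiles <- generate_participants(config, seed = seed)
  trials <- generate_probe_trials(profiles, config, seed = seed + 1L)
  null_fit <- fit_lmm(trials, profiles, null_model_spec(), ddf = "none")
  fit <- fit_lmm(trials, profiles, model_spec(), ddf = ddf)
  jn <- lapply(moderators, function(m) {
    rng <- range(profiles[[m]])
    johnson_neyman(fit, m, range = rng)
  })
  names(jn) <- moderators
  slopes <- lapply(moderators, function(m) simple_slopes(fit, m))
  names(slopes) <- moderators
  out <- list(profiles = profiles, trials = trials, fit = fit,
              null_fit = null_fit, icc = icc(null_fit),
              comparison = compare_models(null_fit, fit),
              jn = jn, slopes = slopes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profiles_csv(profiles, file.path(out_dir, "profiles.csv"))
    write_trials_csv(trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(fit$gamma, file.path(out_dir, "coefficients.csv"),
                     row.names = FALSE)
    report <- list(
      icc = out$icc,
      comparison = out$comparison,
      jn = lapply(jn, function(j) list(boundaries = j$boundaries,
                                       significant = j$significant)),
      slopes = lapply(slopes, function(s) as.data.frame(unclass(s)))
    )
    jsonlite::write_json(report, file.path(out_dir, "moderation_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the network (modularity) experiment end to end
#'
#' For each participant, generates multi-run node time-series panels at each
#' network scale with planted community structure, runs the network pipeline
#' (connectivity, run averaging, thresholding at the configured density,
#' modularity maximization), computes the single-level SPoARC magnitude from
#' generated item-probe trials, and correlates magnitude with modularity at
#' every scale, comparing scales with Steiger tests.
#'
#' A latent participant trait drives both (a) the between-module coupling of
#' the panels at the `linked_scales` (more coupling, lower modularity) and
#' (b) a negative shift of the participant's hand-by-position slope (a larger
#' SPoARC effect), planting a positive modularity-magnitude correlation at
#' those scales only.
#'
#' @param config A [gen_config()] for the behavioral side (default: a
#'   25-participant cohort).
#' @param scales Named integer vector of node counts per network scale.
#' @param linked_scales Scales generatively linked to the SPoARC trait.
#' @param density Edge density retained at binarization.
#' @param n_modules Planted module count per panel.
#' @param coupling_within Within-module coupling of the panels.
#' @param coupling_between_base,coupling_between_gain Between-module coupling
#'   is `base + gain * pnorm(trait)` at linked scales and `base + gain *
#'   pnorm(noise)` elsewhere.
#' @param link_strength Slope shift (ms/position) per trait SD planted into
#'   the RT data.
#' @param runs,timepoints Panel dimensions.
#' @param n_restarts Restarts for the modularity optimizer.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return List: `spoarc` (per-participant magnitudes), `modularity`
#'   (long data frame scale x participant), `summary` (per-scale moment
#'   summaries), `comparison` (a [scale_comparison()] report), `trait`.
#' @export
run_experiment2 <- function(config = gen_config(n_participants = 25),
                            scales = c(whole_brain = 84,
                                       vsowm_attention = 66,
                                       vsowm_spatial_wm = 72),
                            linked_scales = c("vsowm_attention",
                                              "vsowm_spatial_wm"),
                            density = 0.1147, n_modules = 4,
                            coupling_within = 0.9,
                            coupling_between_base = 0.45,
                            coupling_between_gain = 0.4,
                            link_strength = 25,
                            runs = 3, timepoints = 420,
                            n_restarts = 10, seed = NULL, out_dir = NULL) {
  seed <- seed %||% config$seed
  n <- config$n_participants
  set.seed(seed)
  trait <- stats::rnorm(n)
  noise_trait <- stats::rnorm(n)

  profiles <- generate_participants(config, seed = seed + 1L)
  trials <- generate_probe_trials(profiles, config, seed = seed + 2L)
  shift <- -link_strength * trait
  idx <- match(trials$participant_id, profiles$participant_id)
  trials$rt_ms <- trials$rt_ms + shift[idx] * trials$hand * trials$position

  spo <- spoarc_magnitudes(trials)

  modularity <- do.call(rbind, lapply(seq_along(scales), function(si) {
    sc <- names(scales)[si]
    nn <- scales[[si]]
    membership <- rep(seq_len(n_modules), length.out = nn)
    drv <- if (sc %in% linked_scales) trait else noise_trait
    do.call(rbind, lapply(seq_len(n), function(i) {
      cb <- coupling_between_base +
        coupling_between_gain * stats::pnorm(drv[i])
      panel <- generate_modular_timeseries(
        nn, membership, coupling_within, cb, runs = runs,
        timepoints = timepoints,
        seed = seed + 100L * si + i)
      res <- network_pipeline(panel, density = density,
                              n_restarts = n_restarts,
                              seed = seed + 100L * si + i)
      data.frame(scale = sc, participant_id = profiles$participant_id[i],
                 modularity = res$modularity, n_modules = res$n_modules,
                 n_edges = res$n_edges)
    }))
  }))

  by_scale <- lapply(split(modularity, modularity$scale), function(df)
    df[c("participant_id", "modularity")])
  comparison <- scale_comparison(
    spo[c("participant_id", "magnitude")], by_scale)

  summary <- do.call(rbind, lapply(split(modularity, modularity$scale),
                                   function(df) {
    data.frame(scale = df$scale[1], mean = mean(df$modularity),
               sd = stats::sd(df$modularity), min = min(df$modularity),
               max = max(df$modularity),
               skew = sample_skewness(df$modularity),
               kurtosis = sample_kurtosis(df$modularity))
  }))
  rownames(summary) <- NULL

  out <- list(spoarc = spo, modularity = modularity, summary = summary,
              comparison = comparison, trait = trait)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(spo, file.path(out_dir, "spoarc.csv"), row.names = FALSE)
    utils::write.csv(modularity, file.path(out_dir, "modularity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary, correlations = comparison$correlations,
           comparisons = comparison$comparisons),
      file.path(out_dir, "brain_behavior_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
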