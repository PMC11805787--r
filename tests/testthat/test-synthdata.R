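# Synthetic-data generators: determinism, marginal and joint moment
# targets, degenerate configurations, and the structural counts the task
# battery prescribes.

test_that("generators are deterministic given seed and config", {
  cfg <- gen_config(n_participants = 25, seed = 11)
  expect_identical(generate_participants(cfg), generate_participants(cfg))
  p <- generate_participants(cfg)
  t1 <- generate_probe_trials(p, cfg)
  t2 <- generate_probe_trials(p, cfg)
  expect_identical(t1, t2)
  pan1 <- generate_modular_timeseries(10, rep(1:2, 5), 1, 0.2, seed = 3,
                                      timepoints = 20)
  pan2 <- generate_modular_timeseries(10, rep(1:2, 5), 1, 0.2, seed = 3,
                                      timepoints = 20)
  expect_identical(pan1, pan2)
  expect_identical(generate_brain_behavior_pairs(10, 0.4, seed = 2),
                   generate_brain_behavior_pairs(10, 0.4, seed = 2))
})

test_that("level-2 marginals match the configured moments and ranges", {
  cfg <- gen_config(seed = 21)
  p <- generate_participants(cfg)
  expect_equal(nrow(p), 160)
  mom <- default_l2_moments()
  for (i in seq_len(nrow(mom))) {
    v <- p[[mom$measure[i]]]
    expect_true(all(v >= mom$min[i] & v <= mom$max[i]))
    # truncation to the observed range shifts the marginal mean; the sample
    # mean should sit within 3 SE of the truncated-normal expectation
    target <- truncated_normal_mean(mom$mean[i], mom$sd[i], mom$min[i],
                                    mom$max[i])
    expect_lt(abs(mean(v) - target), 3 * mom$sd[i] / sqrt(160),
              label = paste0("|mean(", mom$measure[i], ") - target|"))
  }
  # vsowm is only mildly truncated: its mean also sits within 3 SE of the
  # configured marginal mean itself
  expect_lt(abs(mean(p$vsowm) - 0.65), 3 * 0.18 / sqrt(160))
  expect_true(all(p$handedness %in% 1:2))
  expect_true(all(p$altL %in% 0:1))
  expect_true(all(p$gender %in% 1:2))
})

test_that("copula hits rank-correlation targets; independence case is flat", {
  r <- default_l2_correlations()
  # with the range truncation disabled the copula reproduces the Spearman
  # targets to Monte-Carlo precision
  mom <- default_l2_moments()
  mom$min <- mom$mean - 20 * mom$sd
  mom$max <- mom$mean + 20 * mom$sd
  cfg_wide <- gen_config(n_participants = 4000, l2_moments = mom, seed = 31)
  pw <- generate_participants(cfg_wide)
  expect_lt(abs(cor(pw$siwm, pw$ssowm, method = "spearman") -
                  r["siwm", "ssowm"]), 0.05)
  expect_lt(abs(cor(pw$viwm, pw$vsowm, method = "spearman") -
                  r["viwm", "vsowm"]), 0.05)
  # the default ceiling truncation of the WM capacities attenuates the
  # realized rank correlation, but only moderately
  cfg <- gen_config(n_participants = 4000, seed = 31)
  p <- generate_participants(cfg)
  expect_lt(abs(cor(p$siwm, p$ssowm, method = "spearman") -
                  r["siwm", "ssowm"]), 0.12)
  expect_gt(cor(p$siwm, p$ssowm, method = "spearman"), 0.4)
  cfg0 <- gen_config(n_participants = 2000, l2_correlations = diag(7),
                     seed = 32)
  p0 <- generate_participants(cfg0)
  cors <- cor(as.matrix(p0[default_l2_moments()$measure]))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.08)
})

test_that("probe trials reduce to the intercept in the degenerate config", {
  fx <- default_fixed_effects()
  fx[] <- 0
  fx["intercept"] <- 500
  cfg <- gen_config(n_participants = 5, trials_range = c(10, 10),
                    fixed_effects = fx, sigma2 = 0,
                    tau = matrix(0, 4, 4), seed = 41)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  expect_true(all(tr$rt_ms == 500))
})

test_that("trial counts respect the configured per-participant range", {
  cfg <- gen_config(seed = 51)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  counts <- table(tr$participant_id)
  expect_true(all(counts >= 44 & counts <= 79))
  expect_gte(nrow(tr), 160 * 44)
  expect_lte(nrow(tr), 160 * 79)
  expect_true(all(tr$hand %in% c(-1, 1)))
  expect_true(all(tr$position %in% 1:5))
  expect_true(all(tr$task %in% 1:2))
  expect_true(all(tr$rt_ms > 0))
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(gt$random_effects), 160)
})

test_that("realized random effects approach the configured tau covariance", {
  cfg <- gen_config(n_participants = 4000, trials_range = c(1, 1), seed = 52)
  p <- generate_participants(cfg)
  tr <- generate_probe_trials(p, cfg)
  u <- as.matrix(attr(tr, "ground_truth")$random_effects[, -1])
  tau_hat <- cov(u)
  tau <- default_variance_components()$tau
  # relative error on the dominant variance, absolute on the rest
  expect_lt(abs(tau_hat[1, 1] - tau[1, 1]) / tau[1, 1], 0.1)
  expect_lt(max(abs(tau_hat - tau) / max(tau)), 0.1)
})

test_that("cueing tasks have the stated trial mix and recover the effect", {
  cfg <- gen_config(n_participants = 4, seed = 61)
  p <- generate_participants(cfg)
  p$exo <- 50
  tasks <- generate_attention_wm_trials(p, cfg)
  one <- tasks$exo[tasks$exo$participant_id == p$participant_id[1], ]
  expect_equal(nrow(one), 168)
  expect_equal(sum(one$trial_type == "catch"), 20)
  expect_equal(sum(one$trial_type == "valid"), 126)
  expect_equal(sum(one$trial_type == "invalid"), 22)
  # in the noiseless limit the effect is recovered exactly
  expect_equal(compute_cueing_effect(rep(350, 126), rep(400, 22)), 50)
  # at the default noise level (sd 30 ms) the trimmed estimate sits within
  # 3 SE of the profile value
  se <- sqrt(900 / 126 + 900 / 22)
  expect_lt(abs(compute_cueing_from_trials(one) - 50), 3 * se)
})

test_that("WM capacity 1 yields all nonidentical trials correct", {
  cfg <- gen_config(n_participants = 3, seed = 62)
  p <- generate_participants(cfg)
  p$viwm <- 1
  p$vsowm <- 1
  tasks <- generate_attention_wm_trials(p, cfg)
  wmv <- tasks$wm_verbal
  expect_equal(nrow(wmv[wmv$participant_id == p$participant_id[1], ]), 120)
  nonid <- wmv[wmv$trial_type %in% c("item", "order"), ]
  expect_true(all(nonid$correct == 1))
})

test_that("boa accuracy profile crosses 75% at the profile's breadth", {
  # with many trials per distance the threshold estimator is consistent:
  # accuracy crosses 75% at the planted breadth of 40 cm
  set.seed(63)
  grid <- boa_distance_grid()
  d <- rep(grid, each = 100)
  p_correct <- 0.5 + 0.5 * plogis((40 - d) / 2)
  dense <- data.frame(distance = d, rt_ms = 800,
                      correct = rbinom(length(d), 1, p_correct))
  expect_lt(abs(compute_boa(dense) - 40), 4.5)
  # at the task's 4 trials per distance the literal max rule is dominated by
  # lucky 4/4 runs at far distances; the monotone variant tracks the planted
  # breadth closely
  cfg <- gen_config(n_participants = 15, seed = 63)
  p <- generate_participants(cfg)
  p$boa <- seq(35, 75, length.out = 15)
  tasks <- generate_attention_wm_trials(p, cfg, seed = 64)
  est <- sapply(split(tasks$boa, tasks$boa$participant_id), compute_boa,
                monotone = TRUE)
  est <- est[as.character(p$participant_id)]
  expect_gt(cor(p$boa, est), 0.9)
})

test_that("time-series panels have the declared structure", {
  memb <- rep(1:3, length.out = 12)
  pan <- generate_modular_timeseries(12, memb, 0.8, 0.1, runs = 3,
                                     timepoints = 50, seed = 71)
  expect_equal(dim(pan), c(3, 12, 50))
  expect_false(anyNA(pan))
  expect_identical(attr(pan, "membership"), memb)
  expect_error(generate_modular_timeseries(12, memb[-1], 0.8, 0.1, seed = 1),
               "label every node")
})

test_that("brain-behavior pairs honor the requested correlation structure", {
  x <- generate_brain_behavior_pairs(50, 1, seed = 81)
  expect_equal(cor(x[, 1], x[, 2]), 1, tolerance = 1e-12)
  R <- matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3, 3)
  y <- generate_brain_behavior_pairs(5000, corr_matrix = R, seed = 82)
  expect_lt(max(abs(cor(y) - R)), 0.05)
  expect_error(generate_brain_behavior_pairs(10, 1.5, seed = 1), "true_r")
})

test_that("config validation rejects malformed inputs", {
  expect_error(gen_config(trials_range = c(0, 10)), "within")
  expect_error(gen_config(trials_range = c(50, 161)), "within")
  bad_corr <- diag(7)
  bad_corr[1, 2] <- 0.5  # asymmetric
  expect_error(gen_config(l2_correlations = bad_corr), "symmetric")
  expect_error(gen_config(tau = -diag(4) * 10), "semi-definite")
})
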